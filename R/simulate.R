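# Generative models for angular trajectories: independent per-axis rotational
# Brownian motion plus static Gaussian measurement noise, with geometric
# (memoryless) track lifetimes. Single-population defaults are calibrated so
# the expected ensemble MSD per axis, 2*sigma^2 + 2*D*dt, reproduces the
# reference slope/intercept pairs for the agonist (CCh) and antagonist (BGT)
# conditions.

#' Construct population parameters
#'
#' @param weight mixture fraction in \[0, 1\].
#' @param dTheta,dChi rotational diffusion coefficients, mrad^2/ms.
#' @param sigmaTheta,sigmaChi static noise SD per axis, mrad.
#' @return a [PopulationParams-class].
#' @export
populationParams <- function(weight = 1, dTheta, dChi, sigmaTheta, sigmaChi) {
  new("PopulationParams", weight = weight, dTheta = dTheta, dChi = dChi,
      sigmaTheta = sigmaTheta, sigmaChi = sigmaChi)
}

#' Construct a condition model
#'
#' @param label condition label.
#' @param ligand ligand description (metadata).
#' @param populations list of [PopulationParams-class]; weights sum to 1.
#' @param nTrajectories trajectories to simulate.
#' @param meanLifetime mean trackable span, ms.
#' @param frameInterval frame interval, ms.
#' @param maxDuration maximum record length, ms.
#' @return a [ConditionModel-class].
#' @export
conditionModel <- function(label, ligand = "", populations,
                           nTrajectories, meanLifetime = 0.7,
                           frameInterval = 0.1, maxDuration = 10) {
  new("ConditionModel", label = label, ligand = ligand,
      populations = populations,
      nTrajectories = as.integer(nTrajectories),
      meanLifetime = meanLifetime, frameInterval = frameInterval,
      maxDuration = maxDuration)
}

#' Packaged condition models
#'
#' Single-population defaults calibrated from the reference MSD fits via
#' slope = 2D and intercept = 2 sigma^2:
#' \itemize{
#'   \item CCh (carbamylcholine, 2 uM agonist): D_theta = 10.35,
#'     D_chi = 9.225 mrad^2/ms; sigma_theta^2 = 3.5715,
#'     sigma_chi^2 = 7.398 mrad^2; 157 trajectories.
#'   \item BGT (alpha-bungarotoxin, 0.2 uM antagonist): D_theta = 7.385,
#'     D_chi = 1.1555 mrad^2/ms; sigma_theta^2 = 2.5735,
#'     sigma_chi^2 = 3.103 mrad^2; 176 trajectories.
#' }
#' Both use 0.1 ms frames, a 0.7 ms mean trackable span and 10 ms maximum
#' records.
#'
#' @return a [ConditionModel-class].
#' @export
cchModel <- function() {
  conditionModel("CCh", ligand = "carbamylcholine 2 uM",
    populations = list(populationParams(1, dTheta = 20.70 / 2,
      dChi = 18.45 / 2, sigmaTheta = sqrt(7.143 / 2),
      sigmaChi = sqrt(14.796 / 2))),
    nTrajectories = 157L)
}

#' @rdname cchModel
#' @export
bgtModel <- function() {
  conditionModel("BGT", ligand = "alpha-bungarotoxin 0.2 uM",
    populations = list(populationParams(1, dTheta = 14.77 / 2,
      dChi = 2.311 / 2, sigmaTheta = sqrt(5.147 / 2),
      sigmaChi = sqrt(6.206 / 2))),
    nTrajectories = 176L)
}

#' @rdname cchModel
#' @param gatingWeight mixture weight of the fast-twist gating population.
#' @details \code{cchGatingModel()} is a two-population CCh variant for
#'   heavy-tail experiments: a baseline population with the antagonist-like
#'   twist diffusion plus a gating population whose twist diffusion is chosen
#'   to preserve the ensemble twist slope
#'   (\eqn{w_b D_{BGT} + w_g D_{gate} = D_{CCh}}).
#' @export
cchGatingModel <- function(gatingWeight = 0.3) {
  stopifnot(gatingWeight > 0, gatingWeight < 1)
  dChiBase <- 2.311 / 2
  dChiEns <- 18.45 / 2
  dChiGate <- (dChiEns - (1 - gatingWeight) * dChiBase) / gatingWeight
  sT <- sqrt(7.143 / 2); sC <- sqrt(14.796 / 2)
  conditionModel("CCh", ligand = "carbamylcholine 2 uM",
    populations = list(
      populationParams(1 - gatingWeight, dTheta = 20.70 / 2,
                       dChi = dChiBase, sigmaTheta = sT, sigmaChi = sC),
      populationParams(gatingWeight, dTheta = 20.70 / 2,
                       dChi = dChiGate, sigmaTheta = sT, sigmaChi = sC)),
    nTrajectories = 157L)
}

setMethod("show", "ConditionModel", function(object) {
  cat(sprintf(
    "ConditionModel '%s' (%s): %d populations, %d trajectories, mean life %g ms\n",
    object@label, object@ligand, length(object@populations),
    object@nTrajectories, object@meanLifetime))
})

# hierarchical seed derivation: one 31-bit stream id per (base seed, label,
# index) so per-condition and per-trajectory streams are reproducible
# independently of what else is simulated
deriveSeed <- function(seed, label = "", index = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  h <- (h + 1013904223 * (as.numeric(index) + 1)) %% 2147483647
  as.integer(h)
}

#' Simulate angular trajectories for one condition
#'
#' For each trajectory a population is drawn by weight and a lifetime in
#' frames from a geometric law with mean \code{meanLifetime / frameInterval},
#' clipped to \[2, maxDuration / frameInterval\]. The latent path is
#' independent Brownian motion per axis with per-step variance
#' \eqn{2 D \tau}; observations add i.i.d. Gaussian noise of SD sigma per
#' axis and are re-zeroed to the first observed sample. The expected
#' ensemble MSD per axis is \eqn{2\sigma^2 + 2 D \Delta t} for a single
#' population.
#'
#' Randomness is drawn from a hierarchical stream (condition label ->
#' trajectory index) derived from \code{seed}, so any subset of trajectories
#' is reproducible.
#'
#' @param model a [ConditionModel-class].
#' @param seed integer seed.
#' @param returnTruth also return the per-trajectory generative truth table.
#' @return an [AngularTrajectorySet-class]; with \code{returnTruth = TRUE}, a
#'   list with elements \code{trajectories} and \code{truth} (data.frame:
#'   trajectory_id, population, n_frames, dTheta, dChi, sigmaTheta,
#'   sigmaChi).
#' @export
simulateAngularTrajectories <- function(model, seed = 1L,
                                        returnTruth = FALSE) {
  stopifnot(is(model, "ConditionModel"))
  validObject(model)
  tau <- model@frameInterval
  meanFrames <- model@meanLifetime / tau
  maxFrames <- as.integer(round(model@maxDuration / tau))
  w <- vapply(model@populations, function(p) p@weight, numeric(1))
  rings <- c("Au111", "Au200")
  pieces <- vector("list", model@nTrajectories)
  truth <- vector("list", model@nTrajectories)
  for (i in seq_len(model@nTrajectories)) {
    set.seed(deriveSeed(seed, model@label, i))
    popIdx <- sample.int(length(w), 1, prob = w)
    pop <- model@populations[[popIdx]]
    n <- min(max(stats::rgeom(1, 1 / meanFrames) + 1L, 2L), maxFrames)
    th <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(2 * pop@dTheta * tau)))) +
      stats::rnorm(n, 0, pop@sigmaTheta)
    ch <- cumsum(c(0, stats::rnorm(n - 1, 0, sqrt(2 * pop@dChi * tau)))) +
      stats::rnorm(n, 0, pop@sigmaChi)
    pieces[[i]] <- data.frame(
      trajectory_id = i,
      t_ms = (seq_len(n) - 1) * tau,
      theta_mrad = th - th[1],
      chi_mrad = ch - ch[1],
      ring = rings[(i - 1) %% 2 + 1])
    truth[[i]] <- data.frame(
      trajectory_id = i,
      population = popIdx,
      n_frames = n, dTheta = pop@dTheta, dChi = pop@dChi,
      sigmaTheta = pop@sigmaTheta, sigmaChi = pop@sigmaChi)
  }
  ats <- angularTrajectorySet(do.call(rbind, pieces), frameInterval = tau,
                              conditionLabel = model@label)
  if (returnTruth)
    list(trajectories = ats, truth = do.call(rbind, truth))
  else ats
}
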