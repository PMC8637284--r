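#' Simulation configuration for synthetic paired cohorts
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: log-normal metabolite concentrations with a subject random
#' effect, a class-label (rest/post) shift of configurable sign and size for
#' the discriminant metabolites, quantitation-range censoring at configured
#' per-metabolite rates, TcPO2 recordings with per-limb target minimal DROPs
#' and a chest hypoxemia amount, and severity scores coupled to selected
#' metabolite changes at target Pearson correlations through a
#' bivariate-normal copula.
#'
#' @param nSubjects Number of subjects (each yields one rest + one post
#'   sample).
#' @param panel A [MetabolitePanel-class] (default: full p180 registry).
#' @param discriminantEffects Named numeric: signed log-scale shift (post
#'   minus rest) for each discriminant metabolite; metabolites not named
#'   have no exercise effect.
#' @param subjectSd Log-scale SD of the subject random effect (default 0.5).
#' @param residualSd Log-scale SD of the residual noise (default 0.25).
#' @param censorFractions Named numeric in `[0, 1)`: target fraction of
#'   values below the LLOQ for each censored metabolite.
#' @param severityCorrelations data.frame with columns `metabolite`, `score`
#'   (one of `ABI`, `MWT`, `WELCH`) and `rho` (target Pearson correlation
#'   between the metabolite's exercise-induced log-ratio change and the
#'   score).
#' @param noiseSd TcPO2 trace noise SD (mmHg, default 1).
#' @param exerciseDuration Treadmill exercise duration (s, default 300).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A `simConfig` list (validated).
#' @export
simConfig <- function(nSubjects, panel = buildP180Panel(),
                      discriminantEffects = numeric(),
                      subjectSd = 0.5, residualSd = 0.25,
                      censorFractions = numeric(),
                      severityCorrelations = NULL,
                      noiseSd = 1, exerciseDuration = 300, seed) {
  stopifnot(!missing(seed), nSubjects >= 0)
  ids <- panelDescriptors(panel)$analyte_id
  if (length(discriminantEffects)) {
    stopifnot(!is.null(names(discriminantEffects)),
              all(names(discriminantEffects) %in% ids),
              all(is.finite(discriminantEffects)))
  }
  if (length(censorFractions)) {
    stopifnot(all(names(censorFractions) %in% ids),
              all(censorFractions >= 0 & censorFractions < 1))
  }
  if (!is.null(severityCorrelations)) {
    stopifnot(all(c("metabolite", "score", "rho") %in%
                    colnames(severityCorrelations)),
              all(severityCorrelations$metabolite %in% ids),
              all(severityCorrelations$score %in% c("ABI", "MWT", "WELCH")),
              all(abs(severityCorrelations$rho) < 1),
              !anyDuplicated(severityCorrelations$score))
  }
  structure(list(nSubjects = as.integer(nSubjects), panel = panel,
                 discriminantEffects = discriminantEffects,
                 subjectSd = subjectSd, residualSd = residualSd,
                 censorFractions = censorFractions,
                 severityCorrelations = severityCorrelations,
                 noiseSd = noiseSd, exerciseDuration = exerciseDuration,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Class-typical log-scale baseline concentrations (log uM).
.classBaseline <- c(free_carnitine = log(35), acylcarnitine = log(0.15),
                    amino_acid = log(100), biogenic_amine = log(1),
                    hexose = log(4500), lysoPC = log(2), PC_aa = log(15),
                    PC_ae = log(2), SM = log(15))

#' The study-scale default scenario
#'
#' 39 subjects and the full 188-metabolite panel; 38 metabolites censored
#' below the LLOQ at a 35% rate (so the quantitation filter retains 150);
#' 71 discriminant metabolites among the retained — 4 with decreased
#' post-exercise levels (spermine, putrescine, serine, methionine
#' sulfoxide) and 67 increased (acetylcarnitine C2, C12, C16, alanine,
#' glutamine, acetylornithine, alpha-aminoadipate, 9 sphingomyelins, 7
#' lysoPC and 44 PC species) — at a log-scale effect of 0.6 (about a
#' 1.8-fold change); and two severity-score couplings (trans-4-hydroxy-
#' proline with ABI at rho -0.40, SDMA with MWT at rho 0.39).
#'
#' @param seed Integer seed.
#' @param effectSize Log-scale magnitude of the exercise effect.
#' @return A `simConfig`.
#' @export
paperLikeConfig <- function(seed, effectSize = 0.6) {
  panel <- buildP180Panel()
  d <- panelDescriptors(panel)
  negatives <- c("Spermine", "Putrescine", "Ser", "Met-SO")
  sm9 <- d$analyte_id[d$metabolite_class == "SM"][1:9]
  lyso7 <- d$analyte_id[d$metabolite_class == "lysoPC"][1:7]
  pc_all <- d$analyte_id[d$metabolite_class %in% c("PC_aa", "PC_ae")]
  pc44 <- pc_all[round(seq(1, length(pc_all), length.out = 44))]
  positives <- c("C2", "C12", "C16", "Ala", "Gln", "Ac-Orn", "alpha-AAA",
                 sm9, lyso7, pc44)
  effects <- c(stats::setNames(rep(-effectSize, length(negatives)), negatives),
               stats::setNames(rep(effectSize, length(positives)), positives))
  stopifnot(length(effects) == 71L)
  corr <- data.frame(metabolite = c("t4-OH-Pro", "SDMA"),
                     score = c("ABI", "MWT"), rho = c(-0.40, 0.39))
  protected <- c(names(effects), corr$metabolite)
  candidates <- setdiff(d$analyte_id, protected)
  censored <- withSeed(seed, sample(candidates, 38))
  simConfig(nSubjects = 39, panel = panel, discriminantEffects = effects,
            censorFractions = stats::setNames(rep(0.35, 38), censored),
            severityCorrelations = corr, seed = seed)
}

.subSeeds <- function(seed, n) withSeed(seed, sample.int(2^31 - 2, n))

#' Simulate a paired rest/post metabolome
#'
#' Per subject `i` and metabolite `j`,
#' `log C = mu_j + b_i + s/2 * delta_j + eps`, with `s = -1` at rest and
#' `+1` post exercise, `b_i` the subject random effect and `eps` residual
#' noise. Metabolites with a configured censoring fraction `f` get their
#' LLOQ placed at the `f`-quantile of their marginal distribution, so about
#' `f` of their values fall below range; all other quantitation limits are
#' widened to +/- 8 SD so they never censor. Values are flagged but not
#' altered — clamping is the QC filter's job.
#'
#' @param config A `simConfig` from [simConfig()].
#' @return List with `dataset` (a [PairedMetabolome-class]), `panel` (the
#'   panel with generator-consistent quantitation limits) and `truth`
#'   (ground truth: discriminant ids and signs, censored ids, injected
#'   correlation targets).
#' @export
simulatePairedMetabolome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  d <- panelDescriptors(config$panel)
  nmet <- nrow(d)
  n <- config$nSubjects
  mu <- .classBaseline[d$metabolite_class]
  delta <- stats::setNames(rep(0, nmet), d$analyte_id)
  delta[names(config$discriminantEffects)] <- config$discriminantEffects
  sigma_marg <- sqrt(config$subjectSd^2 + config$residualSd^2 + delta^2 / 4)
  lloq <- exp(mu - 8 * sigma_marg)
  uloq <- exp(mu + 8 * sigma_marg)
  cf <- config$censorFractions
  if (length(cf)) {
    k <- match(names(cf), d$analyte_id)
    lloq[k] <- exp(mu[k] + sigma_marg[k] * stats::qnorm(cf))
  }
  panel <- buildP180Panel(lloq = stats::setNames(lloq, d$analyte_id),
                          uloq = stats::setNames(uloq, d$analyte_id))
  panel <- subsetPanel(panel, d$analyte_id)

  truth <- list(discriminantIds = names(config$discriminantEffects),
                signs = sign(config$discriminantEffects),
                censoredIds = names(cf),
                correlationTargets = config$severityCorrelations)
  if (n == 0L) {
    empty <- matrix(numeric(), nmet, 0, dimnames = list(d$analyte_id, NULL))
    return(list(dataset = PairedMetabolome(empty, character(), character(),
                                           panel = panel),
                panel = panel, truth = truth))
  }
  seeds <- .subSeeds(config$seed, 2)
  conc <- withSeed(seeds[1], {
    b <- stats::rnorm(n, 0, config$subjectSd)
    out <- matrix(NA_real_, nmet, 2 * n)
    for (i in seq_len(n)) {
      eps_r <- stats::rnorm(nmet, 0, config$residualSd)
      eps_p <- stats::rnorm(nmet, 0, config$residualSd)
      out[, 2 * i - 1] <- exp(mu + b[i] - delta / 2 + eps_r)
      out[, 2 * i]     <- exp(mu + b[i] + delta / 2 + eps_p)
    }
    out
  })
  subj <- rep(sprintf("S%02d", seq_len(n)), each = 2)
  cond <- rep(c("rest", "post"), n)
  rownames(conc) <- d$analyte_id
  colnames(conc) <- paste0(subj, "_", cond)
  ds <- PairedMetabolome(conc, subj, cond, panel = panel)
  list(dataset = ds, panel = panel, truth = truth)
}

#' Simulate a multi-probe TcPO2 recording
#'
#' Piecewise trace per probe: a noisy plateau over a 2-min standing rest, a
#' decline during exercise reaching a 60-s trough plateau at the target
#' level, and an exponential return toward baseline over a 10-min recovery.
#' The chest probes decline by the configured hypoxemia amount; each limb
#' probe is placed so that its DROP (limb change minus chest change)
#' reaches the target minimal DROP at the trough. Additive Gaussian noise
#' (`noiseSd`, default 1 mmHg) is applied throughout.
#'
#' @param limbDrops Named numeric of six target minimal DROPs (mmHg, <= 0),
#'   names among the canonical limb sites.
#' @param chestDecrease Target chest decrease during exercise (mmHg, >= 0).
#' @param seed Integer seed.
#' @param noiseSd Trace noise SD (mmHg).
#' @param exerciseDuration Exercise phase length (s).
#' @param samplingHz Sampling rate (default 1 Hz).
#' @return A [TcPO2Recording-class].
#' @export
simulateTcPO2 <- function(limbDrops, chestDecrease = 0, seed,
                          noiseSd = 1, exerciseDuration = 300,
                          samplingHz = 1) {
  stopifnot(all(names(limbDrops) %in% .LIMB_SITES), all(limbDrops <= 0),
            chestDecrease >= 0)
  restDur <- 120; recDur <- 600
  t <- seq(0, restDur + exerciseDuration + recDur, by = 1 / samplingHz)
  ex0 <- restDur; ex1 <- restDur + exerciseDuration
  declineDur <- min(180, max(60, exerciseDuration - 60))
  shape <- function(baseline, trough) {
    y <- rep(baseline, length(t))
    dec <- t >= ex0 & t < ex0 + declineDur
    y[dec] <- baseline + (trough - baseline) * (t[dec] - ex0) / declineDur
    hold <- t >= ex0 + declineDur & t <= ex1
    y[hold] <- trough
    rec <- t > ex1
    y[rec] <- baseline + (trough - baseline) * exp(-(t[rec] - ex1) / 120)
    y
  }
  chestBase <- 65; limbBase <- 60
  sites <- c("chest_left", "chest_right", names(limbDrops))
  P <- matrix(NA_real_, length(t), length(sites),
              dimnames = list(NULL, sites))
  P[, "chest_left"] <- shape(chestBase, chestBase - chestDecrease)
  P[, "chest_right"] <- shape(chestBase, chestBase - chestDecrease)
  for (s in names(limbDrops))
    P[, s] <- shape(limbBase, limbBase + limbDrops[[s]] - chestDecrease)
  P <- P + withSeed(seed, matrix(stats::rnorm(length(P), 0, noiseSd),
                                 nrow(P), ncol(P)))
  TcPO2Recording(t, P, phases = c(rest_start = 0, exercise_start = ex0,
                                  exercise_end = ex1,
                                  recovery_end = ex1 + recDur))
}

#' Simulate a full cohort: metabolome, recordings, severity scores, truth
#'
#' Combines [simulatePairedMetabolome()] with per-subject TcPO2 recordings
#' (limb target minimal DROPs drawn from a truncated normal around -17 mmHg,
#' chest decreases kept below the 5-mmHg hypoxemia threshold) and a severity
#' score table. The `DROPs` severity score is the summed-DROP severity index
#' computed from each simulated recording through the oximetry pipeline;
#' `ABI`, `MWT` and `WELCH` are drawn at study-typical locations and, for
#' the configured couplings, tied to the realised exercise-induced
#' log-ratio change of the target metabolite through a bivariate-normal
#' copula at the target Pearson correlation.
#'
#' @param config A `simConfig`.
#' @return List with `dataset`, `panel`, `truth`, `recordings` (list of
#'   [TcPO2Recording-class]), `scores` (data.frame subject_id, ABI, DROPs,
#'   MWT, WELCH) and `profiles` (the per-subject DROP/hypoxemia targets).
#' @export
simulateCohort <- function(config) {
  met <- simulatePairedMetabolome(config)
  n <- config$nSubjects
  subj <- unique(subjectIds(met$dataset))
  seeds <- .subSeeds(config$seed + 1L, 3 + n)
  profiles <- withSeed(seeds[1], {
    lapply(seq_len(n), function(i) list(
      limbDrops = stats::setNames(pmin(0, stats::rnorm(6, -17, 8)),
                                  .LIMB_SITES),
      chestDecrease = min(4.5, abs(stats::rnorm(1, 1.5, 1.5)))))
  })
  recordings <- lapply(seq_len(n), function(i)
    simulateTcPO2(profiles[[i]]$limbDrops, profiles[[i]]$chestDecrease,
                  seed = seeds[3 + i], noiseSd = config$noiseSd,
                  exerciseDuration = config$exerciseDuration))
  names(recordings) <- names(profiles) <- subj

  dropScore <- vapply(recordings, function(r) dropSummary(r)@severityIndex,
                      numeric(1))
  conc <- concentrations(met$dataset)
  post <- conc[, sampleConditions(met$dataset) == "post", drop = FALSE]
  rest <- conc[, sampleConditions(met$dataset) == "rest", drop = FALSE]
  # couple on the log-ratio change, which is exactly Gaussian under the
  # generator model (a raw-scale delta is heavy-tailed and would let
  # leverage points inflate the realised Pearson correlation)
  deltas <- log(post / rest)  # columns follow subject order

  zmat <- withSeed(seeds[2], matrix(stats::rnorm(3 * n), n, 3,
                                    dimnames = list(subj,
                                                    c("ABI", "MWT", "WELCH"))))
  sc <- config$severityCorrelations
  if (!is.null(sc)) for (r in seq_len(nrow(sc))) {
    zd <- as.numeric(scale(deltas[sc$metabolite[r], ]))
    zmat[, sc$score[r]] <- sc$rho[r] * zd +
      sqrt(1 - sc$rho[r]^2) * zmat[, sc$score[r]]
  }
  scores <- data.frame(
    subject_id = subj,
    ABI = pmin(1.4, pmax(0.15, 0.67 + 0.17 * zmat[, "ABI"])),
    DROPs = dropScore,
    MWT = pmin(900, pmax(60, 420 + 150 * zmat[, "MWT"])),
    WELCH = pmin(50, pmax(0, 25 + 10 * zmat[, "WELCH"])),
    row.names = NULL)
  truth <- met$truth
  truth$profiles <- profiles
  list(dataset = met$dataset, panel = met$panel, truth = truth,
       recordings = recordings, scores = scores, profiles = profiles)
}
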