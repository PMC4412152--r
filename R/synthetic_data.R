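# run code under a seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic screening study
#'
#' Defaults reproduce the structure of the real screen: 511 receptor
#' clones challenged with 73 odorants; runs of twelve 96-well plates
#' transfected from one master plate (one no-odor baseline plate plus
#' eleven odor plates); 85 test wells, five broadly tuned receptors and
#' six Olfr544 standard wells per plate; odorants applied at 100 uM in
#' the primary screen; a no-odor/1/10/100 uM secondary ladder; a
#' half-log dose ladder from 10 nM to 10 mM; and triplicate
#' measurements.
#'
#' @param n_receptors,n_odors Library sizes.
#' @param odors_per_run Odor plates per run (plus one baseline plate).
#' @param primary_conc_uM Primary-screen odorant concentration.
#' @param secondary_ladder_uM Secondary-screen concentrations (0 = no
#'   odor).
#' @param dose_ladder_log10M Dose-response concentrations in log10
#'   molar; the no-odor anchor at -12 is added by the simulator.
#' @param replicates Wells per condition in the secondary and
#'   dose-response phases.
#' @param agonist_density Probability that a receptor/odor pair is a
#'   true agonist pair.
#' @param noise_sigma Additive Gaussian noise, response units.
#' @param plate_gain_sdlog Log-sd of the lognormal per-plate reader
#'   gain.
#' @param well_efficiency_sdlog Log-sd of the lognormal per-well
#'   transfection efficiency (cancels in the firefly/Renilla ratio by
#'   construction).
#' @param rl_mean,rl_cv Mean Renilla photon count and its coefficient of
#'   variation.
#' @param luc_scale Firefly photons per response unit at unit gain.
#' @param baseline_mean,baseline_sd Constitutive (no-odor) receptor
#'   response distribution.
#' @param efficacy_range Uniform range of true agonist response spans.
#' @param log_ec50_range Uniform range of true log10 EC50s (molar).
#' @param standard_response Response span of the Olfr544 standard
#'   (EC50 fixed at 1 uM, challenged at 10 uM).
#' @param vector_baseline Constitutive response of empty-vector wells.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_receptors = 511, n_odors = 73, odors_per_run = 11,
                       primary_conc_uM = 100,
                       secondary_ladder_uM = c(0, 1, 10, 100),
                       dose_ladder_log10M = seq(-8, -2, by = 0.5),
                       replicates = 3, agonist_density = 0.005,
                       noise_sigma = 0.05, plate_gain_sdlog = 0.2,
                       well_efficiency_sdlog = 0.1,
                       rl_mean = 5e5, rl_cv = 0.05, luc_scale = 1000,
                       baseline_mean = 0.2, baseline_sd = 0.05,
                       efficacy_range = c(0.5, 2),
                       log_ec50_range = c(-8, -4),
                       standard_response = 1, vector_baseline = 0.05) {
  if (agonist_density < 0 || agonist_density > 1) {
    stop("config error: agonist_density must be in [0, 1]", call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Ground truth for a synthetic screen
#'
#' Draws the latent state the simulators share: which receptor/odor
#' pairs are true agonists (with latent log EC50 and efficacy), and each
#' receptor's constitutive baseline. The Olfr544 plate standard is
#' always present with EC50 1 uM and span `standard_response`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_truth` with `receptors`, `odors`
#'   (character id vectors in the deposit's integer-id style),
#'   `agonists` (tibble `receptor_id`, `odor_id`, `log_ec50`,
#'   `efficacy`), `baselines` (tibble `receptor_id`,
#'   `baseline_response`), and the `config`.
#' @export
sim_truth <- function(config = sim_config(), seed = 1) {
  .with_seed(seed, {
    receptors <- as.character(1000L + seq_len(config$n_receptors))
    odors <- as.character(3000L + seq_len(config$n_odors))
    pairs <- expand.grid(receptor_id = receptors, odor_id = odors,
                         stringsAsFactors = FALSE)
    hit <- stats::runif(nrow(pairs)) < config$agonist_density
    agonists <- as_tibble(pairs[hit, , drop = FALSE])
    agonists$log_ec50 <- stats::runif(nrow(agonists),
                                      config$log_ec50_range[1],
                                      config$log_ec50_range[2])
    agonists$efficacy <- stats::runif(nrow(agonists),
                                      config$efficacy_range[1],
                                      config$efficacy_range[2])
    baselines <- tibble(
      receptor_id = c(receptors, "Olfr544", .BROAD_RECEPTORS, "vector"),
      baseline_response = c(
        pmax(stats::rnorm(config$n_receptors, config$baseline_mean,
                          config$baseline_sd), 0.01),
        config$baseline_mean, rep(config$baseline_mean, 5),
        config$vector_baseline
      )
    )
    structure(
      list(receptors = receptors, odors = odors, agonists = agonists,
           baselines = baselines, config = config),
      class = "sim_truth"
    )
  })
}

.BROAD_RECEPTORS <- c("Olfr1079", "OR2W1", "Olfr1377", "Olfr73", "Olfr1341")
.STANDARD_RECEPTOR <- "Olfr544"
.STANDARD_ODOR <- "nonanedioic_acid"
.STANDARD_CONC_uM <- 10
.STANDARD_LOG_EC50 <- -6  # 1 uM

# expected response (no noise) of a receptor to an odorant at conc_M molar
.sim_response <- function(truth, receptor_id, odor_id, conc_M) {
  base <- truth$baselines$baseline_response[
    match(receptor_id, truth$baselines$receptor_id)]
  base[is.na(base)] <- truth$config$baseline_mean
  key <- paste(receptor_id, odor_id, sep = "\r")
  akey <- paste(truth$agonists$receptor_id, truth$agonists$odor_id,
                sep = "\r")
  idx <- match(key, akey)
  eff <- ifelse(is.na(idx), 0, truth$agonists$efficacy[idx])
  ec50 <- ifelse(is.na(idx), 1, 10^truth$agonists$log_ec50[idx])
  std <- receptor_id == .STANDARD_RECEPTOR & odor_id == .STANDARD_ODOR
  eff[std] <- truth$config$standard_response
  ec50[std] <- 10^.STANDARD_LOG_EC50
  base + eff * conc_M / (conc_M + ec50)
}

#' Simulate one primary-screen run of twelve plates
#'
#' One run shares a transfection master plate: every plate carries the
#' same receptors in the same wells. One plate receives no odor in its
#' test wells (the baseline plate, concentration sentinel 9999); the
#' other eleven are each challenged with a different odorant at the
#' primary concentration. Firefly counts follow
#' `gain * efficiency * luc_scale * (baseline + efficacy * occupancy + noise)`
#' with lognormal per-plate gain and per-well transfection efficiency;
#' Renilla counts are `efficiency * rl_mean * (1 + noise)`, so the
#' firefly/Renilla ratio cancels the well efficiency and per-plate
#' standardization cancels the gain.
#'
#' @param config A [sim_config()].
#' @param truth A [sim_truth()]; defaults to a fresh draw under `seed`.
#' @param seed Integer seed; the same seed reproduces the run exactly.
#' @param receptors Receptor ids for the 85 test wells (recycled or
#'   truncated to the layout); defaults to the first 85 in `truth`.
#' @param odors Odor ids for the run's odor plates; defaults to the
#'   first `odors_per_run` in `truth`.
#' @param run_date Date of the run.
#' @param layout A [plate_layout()].
#' @return A list with `records` (primary-screen well tibble covering
#'   `length(odors) + 1` plates of 96 wells) and `truth`.
#' @export
simulate_primary_run <- function(config = sim_config(), truth = NULL,
                                 seed = 1, receptors = NULL, odors = NULL,
                                 run_date = as.Date("2011-06-01"),
                                 layout = plate_layout()) {
  if (is.null(truth)) truth <- sim_truth(config, seed = seed)
  config <- truth$config
  if (is.null(receptors)) {
    receptors <- truth$receptors[seq_len(min(length(layout$test_wells),
                                             length(truth$receptors)))]
  }
  if (is.null(odors)) {
    odors <- truth$odors[seq_len(min(config$odors_per_run,
                                     length(truth$odors)))]
  }
  .with_seed(seed + 1L, {
    n_test <- length(receptors)
    test_wells <- layout$test_wells[seq_len(n_test)]
    # well -> receptor map shared by all plates of the run
    well_map <- tibble(
      well_index = c(test_wells, layout$broad_wells,
                     layout$standard_agonist_wells,
                     layout$standard_diluent_wells),
      receptor_id = c(receptors, .BROAD_RECEPTORS,
                      rep(.STANDARD_RECEPTOR, 6))
    )
    plate_odors <- c(NA_character_, odors)  # first plate is the baseline
    records <- vector("list", length(plate_odors))
    for (p in seq_along(plate_odors)) {
      odor <- plate_odors[p]
      is_baseline <- is.na(odor)
      plate_id <- sprintf("%s_P%02d", format(run_date, "%Y%m%d"), p)
      gain <- stats::rlnorm(1, 0, config$plate_gain_sdlog)
      eff <- stats::rlnorm(nrow(well_map), 0, config$well_efficiency_sdlog)

      role_std_ag <- well_map$well_index %in% layout$standard_agonist_wells
      role_std_di <- well_map$well_index %in% layout$standard_diluent_wells
      no_odor <- role_std_di | (!role_std_ag & is_baseline)
      odor_id <- rep(if (is_baseline) "none" else odor, nrow(well_map))
      odor_id[role_std_ag] <- .STANDARD_ODOR
      odor_id[no_odor] <- "none"
      conc_uM <- rep(if (is_baseline) NA_real_ else config$primary_conc_uM,
                     nrow(well_map))
      conc_uM[role_std_ag] <- .STANDARD_CONC_uM
      conc_uM[no_odor] <- NA_real_

      conc_M <- ifelse(is.na(conc_uM), 0, conc_uM * 1e-6)
      mu <- .sim_response(truth, well_map$receptor_id, odor_id, conc_M)
      resp <- pmax(mu + stats::rnorm(nrow(well_map), 0, config$noise_sigma),
                   1e-4)
      luc <- gain * eff * config$luc_scale * resp
      rl <- eff * config$rl_mean *
        pmax(1 + stats::rnorm(nrow(well_map), 0, config$rl_cv), 1e-3)

      records[[p]] <- tibble(
        plate_id = plate_id, well_index = well_map$well_index,
        concentration_uM = conc_uM, luc_counts = luc, rl_counts = rl,
        receptor_id = well_map$receptor_id, odor_id = odor_id,
        date = run_date, no_odor = no_odor
      )
    }
    records <- bind_rows(records)
    attr(records, "kind") <- "primary"
    list(records = records, truth = truth)
  })
}

#' Simulate a full primary screen
#'
#' Partitions the receptor library into 85-well transfection batches and
#' the odorant panel into runs of `odors_per_run`, then simulates one
#' [simulate_primary_run()] per batch pair, each on its own date.
#'
#' @inheritParams simulate_primary_run
#' @param start_date Date of the first run; successive runs fall on
#'   successive days.
#' @return A list with `records` and `truth`.
#' @export
simulate_primary_screen <- function(config = sim_config(), truth = NULL,
                                    seed = 1,
                                    start_date = as.Date("2011-06-01"),
                                    layout = plate_layout()) {
  if (is.null(truth)) truth <- sim_truth(config, seed = seed)
  config <- truth$config
  n_wells <- length(layout$test_wells)
  rec_batches <- split(truth$receptors,
                       (seq_along(truth$receptors) - 1L) %/% n_wells)
  odor_batches <- split(truth$odors,
                        (seq_along(truth$odors) - 1L) %/% config$odors_per_run)
  runs <- vector("list", length(rec_batches) * length(odor_batches))
  k <- 0L
  for (rb in rec_batches) {
    for (ob in odor_batches) {
      k <- k + 1L
      runs[[k]] <- simulate_primary_run(
        config, truth, seed = seed + 1000L * k, receptors = rb, odors = ob,
        run_date = start_date + k - 1L, layout = layout
      )$records
    }
  }
  records <- bind_rows(runs)
  attr(records, "kind") <- "primary"
  list(records = records, truth = truth)
}

#' Simulate secondary-screen triplicates for selected pairs
#'
#' Each pair is measured in triplicate at the no-odor control (rows keep
#' the pair's odor id with concentration 0, matching the deposit) and at
#' 1, 10 and 100 uM. Responses are already firefly/Renilla normalized.
#' Pairs absent from the truth's agonist list respond at baseline only.
#'
#' @param pairs Tibble with `receptor_id`, `odor_id`.
#' @param config A [sim_config()] (taken from `truth` when given).
#' @param truth A [sim_truth()].
#' @param seed Integer seed.
#' @param run_date Date stamped on the records.
#' @return A secondary-screen well tibble
#'   (`replicates * length(secondary_ladder_uM)` rows per pair).
#' @export
simulate_secondary <- function(pairs, config = sim_config(), truth = NULL,
                               seed = 1, run_date = as.Date("2011-07-01")) {
  if (is.null(truth)) truth <- sim_truth(config, seed = seed)
  config <- truth$config
  .with_seed(seed + 2L, {
    grid <- expand.grid(
      i = seq_len(nrow(pairs)),
      concentration_uM = config$secondary_ladder_uM,
      rep = seq_len(config$replicates)
    )
    mu <- .sim_response(truth, pairs$receptor_id[grid$i],
                        pairs$odor_id[grid$i], grid$concentration_uM * 1e-6)
    out <- tibble(
      date = run_date,
      receptor_id = pairs$receptor_id[grid$i],
      odor_id = pairs$odor_id[grid$i],
      concentration_uM = grid$concentration_uM,
      normalized_luc = mu + stats::rnorm(nrow(grid), 0, config$noise_sigma)
    )
    out <- arrange(out, .data$receptor_id, .data$odor_id,
                   .data$concentration_uM)
    attr(out, "kind") <- "secondary"
    out
  })
}

#' Simulate receptor and odorant metadata tables
#'
#' Companion generator for the clone-library and odorant-panel schemas:
#' random in-frame coding sequences and gene-style labels for receptors,
#' and name/CAS/CID/SMILES stubs for odorants. Purely synthetic — the
#' sequences and structures are placeholders that exercise the parsers,
#' not real genes or chemicals.
#'
#' @param truth A [sim_truth()].
#' @param seed Integer seed.
#' @return A list with `receptors` (kind `"receptor"`) and `odors`
#'   (kind `"odor"`) tibbles.
#' @export
simulate_metadata <- function(truth, seed = 1) {
  .with_seed(seed + 4L, {
    n_r <- length(truth$receptors)
    seqs <- vapply(seq_len(n_r), function(i) {
      paste(sample(c("A", "C", "G", "T"), 3L * sample(300:320, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
    receptors <- tibble(
      receptor_id = truth$receptors,
      gene_label = sprintf("OR%dX%d", sample(1:14, n_r, TRUE),
                           sample(1:9, n_r, TRUE)),
      nucleotide_seq = seqs
    )
    attr(receptors, "kind") <- "receptor"
    n_o <- length(truth$odors)
    odors <- tibble(
      odor_id = truth$odors,
      cas_number = sprintf("%d-%02d-%d", sample(50:9999, n_o, TRUE),
                           sample(0:99, n_o, TRUE), sample(0:9, n_o, TRUE)),
      odor_name = sprintf("odorant_%s", truth$odors),
      cid = sample.int(100000L, n_o),
      smiles = vapply(sample(2:8, n_o, TRUE), function(k) {
        paste0("C", paste(rep("C", k), collapse = ""), "O")
      }, character(1))
    )
    attr(odors, "kind") <- "odor"
    list(receptors = receptors, odors = odors)
  })
}

#' Simulate dose-response series with matched empty-vector controls
#'
#' For each pair, triplicate responses on the half-log dose ladder plus
#' the no-odor anchor (coded -12 log10 molar), and a matched
#' empty-vector series (`receptor_id = "vector"`, zero efficacy) for the
#' same odorant, as used by the extra sum-of-squares comparison.
#'
#' @inheritParams simulate_secondary
#' @param vector_controls Emit the matched vector series (default
#'   `TRUE`).
#' @return A dose-response well tibble.
#' @export
simulate_dose_response <- function(pairs, config = sim_config(),
                                   truth = NULL, seed = 1,
                                   run_date = as.Date("2011-08-01"),
                                   vector_controls = TRUE) {
  if (is.null(truth)) truth <- sim_truth(config, seed = seed)
  config <- truth$config
  .with_seed(seed + 3L, {
    ladder <- c(-12, config$dose_ladder_log10M)
    series <- pairs
    if (vector_controls) {
      vec <- tibble(receptor_id = "vector",
                    odor_id = unique(pairs$odor_id))
      series <- bind_rows(pairs[, c("receptor_id", "odor_id")], vec)
    }
    grid <- expand.grid(
      i = seq_len(nrow(series)),
      concentration_log10M = ladder,
      rep = seq_len(config$replicates)
    )
    conc_M <- ifelse(grid$concentration_log10M == -12, 0,
                     10^grid$concentration_log10M)
    mu <- .sim_response(truth, series$receptor_id[grid$i],
                        series$odor_id[grid$i], conc_M)
    out <- tibble(
      concentration_log10M = grid$concentration_log10M,
      normalized_luc = mu + stats::rnorm(nrow(grid), 0, config$noise_sigma),
      receptor_id = series$receptor_id[grid$i],
      odor_id = series$odor_id[grid$i],
      date = run_date,
      no_odor = grid$concentration_log10M == -12
    )
    out <- arrange(out, .data$receptor_id, .data$odor_id,
                   .data$concentration_log10M)
    attr(out, "kind") <- "dose"
    out
  })
}
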