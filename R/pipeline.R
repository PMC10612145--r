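#' Run the simulate-fit-summarize demonstration pipeline
#'
#' End-to-end driver over a model registry: for each selected protein it
#' (1) forward-simulates a 2:1 probe competition and estimates the
#' average per-site and stepwise constants, (2) simulates a pH titration
#' at the protein's reference pKa' and refits it, (3) simulates a
#' fluorescent-probe transfer isotherm from the weakest-site sub-model
#' and recovers those constants, (4) simulates and refits an oxidation
#' kinetic trace, and (5) writes a speciation profile over pZn. Results
#' are written as a constants summary (CSV + JSON) plus one tidy
#' speciation CSV per protein. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config Either a list or a path to a YAML/JSON file with
#'   fields: `out_dir` (required), `seed` (default 1), `noise_sigma`
#'   (fraction of dynamic range, default 0.02), `proteins` (names,
#'   default: all in the registry), `experiments` (subset of
#'   `"par"`, `"ph"`, `"znaf"`, `"kinetics"`, `"speciation"`),
#'   `registry` (path; default: bundled fixture registry).
#' @return Invisibly, the summary data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  seed <- as.integer(config$seed %||% 1L)
  sigma <- as.numeric(config$noise_sigma %||% 0.02)
  kinds <- config$experiments %||%
    c("par", "ph", "znaf", "kinetics", "speciation")
  known <- c("par", "ph", "znaf", "kinetics", "speciation")
  if (!all(kinds %in% known))
    stop("unknown experiment kind(s): ",
         paste(setdiff(kinds, known), collapse = ", "), call. = FALSE)
  registry <- if (is.null(config$registry)) make_fixture_models()
              else load_models(config$registry)
  prot_names <- config$proteins %||% names(registry$proteins)
  if (length(prot_names) == 0L) {
    warning("no proteins selected: nothing to do")
    return(invisible(data.frame()))
  }
  missing <- setdiff(prot_names, names(registry$proteins))
  if (length(missing))
    stop("proteins not in registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  par_probe <- registry$probes$par %||% probe_2to1()
  znaf_probe <- registry$probes$znaf %||% probe_1to1()

  rows <- vector("list", length(prot_names))
  for (i in seq_along(prot_names)) {
    model <- registry$proteins[[prot_names[i]]]
    row <- list(protein = model$name, n_sites = model$n_sites)
    sd_base <- seed * 1000L + i * 10L

    if ("par" %in% kinds) {
      obs <- simulate_par_transfer(model, 1e-6, 2e-4, par_probe,
                                   noise = noise_spec(sigma, sd_base + 1L))
      row$par_transferred_eq <- obs$transferred_eq
      av <- average_persite_kd(obs, par_probe)
      row$neg_log_kd_av <- unname(av$parameters["neg_log_kd_av"])
      n_steps <- min(max(ceiling(obs$transferred_eq), 1L), 3L)
      st <- stepwise_kd_from_transfer(obs, par_probe, n_steps)
      row$stepwise_model <- names(st$parameters)[1L]
      row$neg_log_kd_stepwise <- unname(st$parameters[1L])
    }
    if ("ph" %in% kinds) {
      pka <- attr(model, "pka_prime") %||% 4.8
      tit <- simulate_ph_titration(pka, n = 2, plateaus = c(0.02, 0.45),
                                   grid = seq(2.6, 7.8, by = 0.2),
                                   noise = noise_spec(sigma, sd_base + 2L))
      hf <- fit_hill_ph(tit)
      row$pka_true <- pka
      row$pka_fit <- if (hf$converged) unname(hf$parameters["pka"]) else NA_real_
    }
    if ("znaf" %in% kinds) {
      wk <- weak_site_recovery(model, znaf_probe, sigma, sd_base + 3L)
      row <- c(row, wk)
    }
    if ("kinetics" %in% kinds) {
      k_true <- 0.01
      tr <- simulate_kinetic_trace(k_true, amplitude = 0.12, offset = 0.01,
                                   t_grid = seq(0, 600, by = 15),
                                   noise = noise_spec(sigma, sd_base + 4L))
      kf <- fit_pseudo_first_order(tr)
      row$k_obsd_true <- k_true
      row$k_obsd_fit <- if (kf$converged) unname(kf$parameters["k_obsd"])
                        else NA_real_
    }
    if ("speciation" %in% kinds) {
      prof <- speciation_vs_pzn(model, seq(4, 18, by = 0.05))
      write_speciation_csv(
        prof, file.path(out_dir, paste0("speciation_", model$name, ".csv")))
    }
    rows[[i]] <- row
  }
  all_names <- unique(unlist(lapply(rows, names)))
  summary <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names])
  }))
  write_titration_csv(summary, file.path(out_dir, "summary.csv"),
                      metadata = list(seed = seed, noise_sigma = sigma))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}

# Simulate a fluorescent-probe transfer isotherm from the weakest-site
# sub-model of `model` and refit it; returns truth and estimates.
weak_site_recovery <- function(model, probe, sigma, seed) {
  steps <- model$pkd_steps
  n <- model$n_sites
  coop <- identical(attr(model, "weak_release"), "cooperative")
  if (coop) {
    sizes <- attr(model, "group_sizes")
    n_coop <- if (!is.null(sizes) && !is.na(sizes["weak"])) sizes[["weak"]]
              else sum(steps == steps[n])
    pkd_true <- steps[n]
    pzn <- seq(pkd_true + 2, pkd_true - 2, by = -0.2)
    t_eq <- n_coop / (1 + 10^(n_coop * (pkd_true - pzn)))
    iso <- data.frame(pzn = pzn,
                      transferred_eq = apply_noise(t_eq, noise_spec(sigma, seed)))
    fit <- fit_weak_sites_znaf(iso, cooperative = TRUE, n_coop = n_coop)
    return(list(weak_pkd1_true = pkd_true,
                weak_pkd1_fit = if (fit$converged)
                  unname(fit$parameters["pkd"]) else NA_real_))
  }
  # sites the fluorescent probe can mobilize (within ~2.5 log of its Kd)
  reach <- probe$pkd + 2.5
  weak_idx <- which(steps <= reach)
  weak_idx <- weak_idx[weak_idx > n - 2L]          # at most the two weakest
  if (length(weak_idx) == 0L) weak_idx <- n
  # generator: the weakest sites as independent sites (the estimator's
  # forward model), composed into the equivalent macroscopic ladder
  sub <- independent_sites_model(model$name, steps[min(weak_idx):n])
  n_weak <- length(min(weak_idx):n)
  iso <- simulate_znaf_transfer_isotherm(
    sub, 5e-7, probe_grid = 10^seq(-7.3, -5.3, by = 0.1), probe,
    noise = noise_spec(sigma, seed))
  fit <- fit_weak_sites_znaf(iso, n_weak = n_weak, protein_total = 5e-7)
  out <- list(weak_pkd1_true = steps[n],
              weak_pkd1_fit = if (fit$converged)
                unname(fit$parameters[n_weak]) else NA_real_)
  if (n_weak == 2L) {
    out$weak_pkd2_true <- steps[n - 1L]
    out$weak_pkd2_fit <- if (fit$converged)
      unname(fit$parameters["pkd1"]) else NA_real_
  }
  out
}
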