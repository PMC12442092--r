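#' Read free-energy profiles from CSV
#'
#' Expected columns: `system_id,label,role,G_rel_kcal` (pre-referenced
#' relative energies, kcal/mol), or the raw form
#' `system_id,label,role,E_BS2,H_corr,S,unit` which is converted through
#' [gibbs_energy()]. One profile is returned per `system_id`, in file order.
#' Malformed rows are rejected with their line number.
#'
#' @param path CSV file with a header row (UTF-8).
#' @param state a [standard_state()] used for the raw form and attached to
#'   every profile.
#' @return Named list of [gibbs_profile()]s.
#' @export
read_profile_csv <- function(path, state = standard_state(T = 393.15)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("system_id", "label", "role")
  if (!all(base %in% names(df)))
    stop("profile CSV needs columns: ", paste(base, collapse = ", "),
         call. = FALSE)
  raw_form <- all(c("E_BS2", "H_corr", "S", "unit") %in% names(df))
  if (!raw_form && !"G_rel_kcal" %in% names(df))
    stop("profile CSV needs either G_rel_kcal or E_BS2,H_corr,S,unit columns",
         call. = FALSE)
  num_cols <- if (raw_form) c("E_BS2", "H_corr", "S") else "G_rel_kcal"
  for (cl in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cl]]))))
    if (length(bad))
      stop(sprintf("missing or non-numeric `%s` at data row %s of %s",
                   cl, paste(bad, collapse = ", "), basename(path)),
           call. = FALSE)
  }
  out <- lapply(split(df, factor(df$system_id, unique(df$system_id))),
                function(g) {
    if (raw_form) {
      units <- unique(g$unit)
      if (length(units) != 1L)
        stop("mixed unit tags within system ", g$system_id[1L], call. = FALSE)
      recs <- lapply(seq_len(nrow(g)), function(i)
        thermo_record(g$label[i], g$E_BS2[i], g$H_corr[i], g$S[i],
                      role = g$role[i], unit = units))
      assemble_profile(recs, system_id = g$system_id[1L], state = state)
    } else {
      assemble_profile(data.frame(label = g$label, role = g$role,
                                  G_rel = g$G_rel_kcal),
                       system_id = g$system_id[1L], state = state)
    }
  })
  out
}

#' Write free-energy profiles to CSV
#'
#' @param profiles a [gibbs_profile()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "gibbs_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(system_id = paste(p$system_id, collapse = "+"),
               label = p$points$label, role = p$points$role,
               G_rel_kcal = p$points$G_rel)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write substrate descriptor tables
#'
#' Plain CSV keyed by `substrate_id`; duplicated ids are rejected. The
#' write/read round trip preserves values to full double precision.
#'
#' @param path CSV path.
#' @return data.frame of descriptors.
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"substrate_id" %in% names(df))
    stop("descriptor CSV needs a substrate_id column", call. = FALSE)
  if (anyDuplicated(df$substrate_id))
    stop("duplicated substrate id(s) in ", basename(path), call. = FALSE)
  df
}

#' @rdname read_descriptor_csv
#' @param table data.frame to write.
#' @export
write_descriptor_csv <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a barrier report as JSON
#'
#' @param result a [overall_barrier()] result.
#' @param system_id system identifier recorded in the report.
#' @param path output JSON path.
#' @export
write_barrier_report <- function(result, system_id, path) {
  stopifnot(inherits(result, "barrier_result"))
  jsonlite::write_json(
    list(system_id = system_id, delta_G_dd = result$delta_G_dd,
         determining_ts = result$determining_ts,
         resting_intermediate = result$resting_intermediate,
         regime = result$regime),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the pipeline stages in order -- profiles, barrier extraction,
#' 16-hour microkinetics, barrier sweep with feasibility limit, synthetic
#' substrate library with the multilinear barrier regression and its
#' cross-validations -- and consolidates everything into a single report,
#' optionally written to `<outdir>/report.json`. A rerun with the same
#' config is reproducible because every stochastic stage is seeded from
#' `config$seed`.
#'
#' @param config a list (or path to a JSON/YAML file) with optional fields:
#'   `profile_csv` (path; default: the packaged reference acetone profile),
#'   `conditions` (arguments to [sim_conditions()]), `sweep`
#'   (`list(min, max)` of integer barriers; `NULL` skips the stage), `mlr`
#'   (arguments to [generator_spec()]; `NULL` skips), `seed`, `outdir`.
#' @return The report, a nested list, invisibly when written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("`config` must be a list or a file path",
                             call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cond <- do.call(sim_conditions, as.list(config$conditions))

  profiles <- if (is.null(config$profile_csv)) {
    list(`RF-9-BBN+acetone` = cu_acetone_profile())
  } else read_profile_csv(config$profile_csv, standard_state(T = cond$T))

  report <- list(seed = seed)
  report$profiles <- lapply(profiles, function(p) {
    br <- overall_barrier(p)
    tr <- simulate_network(build_network(p), cond)
    list(system_id = paste(p$system_id, collapse = "+"),
         delta_G_dd = br$delta_G_dd, determining_ts = br$determining_ts,
         resting_intermediate = br$resting_intermediate, regime = br$regime,
         yield_16h = product_yield(tr, cond$t_end))
  })

  if (!is.null(config$sweep)) {
    gs <- generator_spec(seed = seed)
    base <- generate_profile(23.6, gs, system_id = "sweep-template")
    sw <- barrier_sweep(base, seq(config$sweep$min, config$sweep$max), cond)
    report$sweep <- list(table = as.data.frame(sw),
                         feasibility_limit_kcal = feasibility_limit(sw))
  }

  if (!is.null(config$mlr)) {
    gs <- do.call(generator_spec, c(as.list(config$mlr), list(seed = seed)))
    subs <- generate_substrates(gs)
    bar <- generate_barriers(subs, gs)
    fit <- fit_barrier_mlr(bar[c("N_prime", "eps_lumo_eV")], bar$delta_G)
    report$mlr <- list(
      n = fit$n,
      coef_std = as.list(fit$coef_std),
      coef_raw = as.list(fit$coef_raw),
      fit = unclass(fit$stats),
      loo = unclass(loo_cv(bar[c("N_prime", "eps_lumo_eV")],
                           bar$delta_G))[c("R2", "rmse", "mae", "n")],
      kfold = unclass(kfold_cv(bar[c("N_prime", "eps_lumo_eV")],
                               bar$delta_G, k = 4,
                               seed = seed))[c("R2", "rmse", "mae", "n")])
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}
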