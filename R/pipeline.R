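## End-to-end ensemble study: build base models from topography specs,
## generate jitter ensembles emulating level-of-theory variation, locate
## each member's minimum-energy crossing point, characterize and classify
## it, and summarize quadrant occupancy and outliers.

#' Study configuration
#'
#' Validates and normalizes a study configuration, either given as a list
#' or read from a YAML/JSON file.  Each system entry needs `label`,
#' `pitch`, and optionally `asymmetry`, `tilt_magnitude`, `tilt_heading`,
#' `n_dim` (default 2), `e_x` (default 0), `jitter_scale` (default 0),
#' `n_members` (default 1), `seed` (default 1).  Top-level fields:
#' `optimizer` (`"projection"` or `"penalty"`, plus optional numeric
#' overrides `gap_tol`, `step_tol`, `max_iter`, `penalty_weight`,
#' `smoothing`), `epsilon` (classification boundary tolerance, default
#' 0.02), `output_dir` (optional).
#'
#' @param x A list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated `study_config` object.
#' @export
study_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE))
      yaml::read_yaml(x) else jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  if (is.null(x$systems) || !length(x$systems))
    stop("config needs a non-empty 'systems' list")
  sys_default <- list(asymmetry = 0, tilt_magnitude = 0, tilt_heading = 0,
                      n_dim = 2L, e_x = 0, jitter_scale = 0,
                      n_members = 1L, seed = 1L)
  systems <- lapply(x$systems, function(s) {
    if (is.null(s$label) || is.null(s$pitch))
      stop("every system needs 'label' and 'pitch'")
    s <- modifyList(sys_default, s)
    if (s$n_members < 1L) stop("ensemble size must be >= 1")
    s$seed <- as.integer(s$seed)
    s
  })
  opt_default <- list(name = "projection", gap_tol = 1e-6, step_tol = 1e-6,
                      max_iter = 500L, penalty_weight = 5, smoothing = 0.02)
  optimizer <- modifyList(opt_default, if (is.null(x$optimizer)) list()
                          else x$optimizer)
  if (!optimizer$name %in% c("projection", "penalty"))
    stop("optimizer name must be 'projection' or 'penalty'")
  structure(list(systems = systems, optimizer = optimizer,
                 epsilon = if (is.null(x$epsilon)) 0.02 else x$epsilon,
                 output_dir = x$output_dir),
            class = "study_config")
}

## optimize + characterize + classify one model; never throws on
## optimization failure (records converged = FALSE instead)
characterize_member <- function(model, system, member, optimizer, epsilon) {
  q0 <- numeric(model$n_dim)
  q0[1:2] <- c(0.7, -0.7)   # fixed off-seam start, deterministic
  opt_params <- optimizer[setdiff(names(optimizer), "name")]
  res <- if (optimizer$name == "penalty")
    optimize_penalty(model, q0, opt_params)
  else optimize_projection(model, q0, opt_params)
  rec <- list(system = system, member = member,
              converged = res$converged,
              q_star = res$q_star, gap = res$gap,
              mean_energy = res$mean_energy,
              n_iterations = res$n_iterations,
              provenance = list(optimizer = optimizer$name,
                                gap_tol = optimizer$gap_tol,
                                step_tol = optimizer$step_tol,
                                seed = model$seed))
  if (res$converged) {
    ev <- adiabatic_eval(model, res$q_star, degeneracy_tol = 2 * res$gap + 1e-300)
    tp <- compute_topography(
      extract_branching_vectors(ev, gap_tol = 10 * optimizer$gap_tol))
    cl <- classify(tp, epsilon)
    rec$topography <- tp
    rec$class <- cl
    rec$quadrant <- quadrant_label(cl)
  } else {
    rec$quadrant <- NA_character_
  }
  structure(rec, class = "meci_record")
}

#' @export
print.meci_record <- function(x, ...) {
  cat(sprintf("[%s | %s] %s", x$system, x$member,
              if (x$converged) x$quadrant else "UNCONVERGED"))
  if (x$converged)
    cat(sprintf("  (P = %.3f, B = %.3f)", x$topography$p_value,
                x$topography$b_value))
  cat("\n")
  invisible(x)
}

#' Run the full ensemble study
#'
#' For every configured system: build the base model from its topography
#' spec, draw `n_members` jittered copies (member 1 is always the
#' unperturbed base model), locate each member's minimum-energy crossing
#' point, characterize and classify it.  Unconverged members are recorded,
#' never dropped.  The run is fully deterministic under the config's
#' seeds.  Outliers are members whose quadrant differs from their system's
#' modal quadrant; a tie for the mode is flagged on the system and no
#' outlier call is made there.
#'
#' @param config A [study_config()] (or anything it accepts).
#' @return List with `records` (all `meci_record`s), `quadrant_table`
#'   (from [quadrant_summary()]), `outliers` (data frame system, member,
#'   quadrant, modal_quadrant), `mode_ties` (labels of systems whose modal
#'   quadrant is tied) and `log` (one line per member).  When the config
#'   names an `output_dir`, also writes `records.json`, `scatter.csv`,
#'   `quadrant.csv`, `run.log` and an echo of the config there.
#' @export
run_study <- function(config) {
  config <- if (inherits(config, "study_config")) config else study_config(config)
  records <- list()
  log_lines <- character()
  for (s in config$systems) {
    base <- build_model(topography_spec(s$pitch, s$asymmetry,
                                        s$tilt_magnitude, s$tilt_heading),
                        n_dim = s$n_dim, e_x = s$e_x, seed = s$seed)
    for (m in seq_len(s$n_members)) {
      model <- if (m == 1L) base
      else perturb_model(base, s$jitter_scale, child_seed(s$seed, m))
      member <- sprintf("m%02d", m)
      rec <- characterize_member(model, s$label, member,
                                 config$optimizer, config$epsilon)
      records[[length(records) + 1L]] <- rec
      log_lines <- c(log_lines, sprintf(
        "INFO system=%s member=%s seed=%d iters=%d gap=%.3e class=%s",
        s$label, member, model$seed, rec$n_iterations, rec$gap,
        if (is.na(rec$quadrant)) "unconverged" else rec$quadrant))
    }
  }
  qt <- quadrant_summary(records)
  out <- outlier_flags(records)
  result <- list(records = records, quadrant_table = qt,
                 outliers = out$outliers, mode_ties = out$mode_ties,
                 log = log_lines)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    export_records_json(records,
                        file.path(config$output_dir, "records.json"))
    export_scatter(records, file.path(config$output_dir, "scatter.csv"))
    write_quadrant_csv(qt, file.path(config$output_dir, "quadrant.csv"))
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                digits = NA, null = "null"),
               file.path(config$output_dir, "config-echo.json"))
  }
  result
}

## modal quadrant per system and members deviating from it
outlier_flags <- function(records) {
  conv <- Filter(function(r) r$converged, records)
  outliers <- data.frame(system = character(), member = character(),
                         quadrant = character(),
                         modal_quadrant = character(),
                         stringsAsFactors = FALSE)
  ties <- character()
  for (sys in unique(vapply(conv, `[[`, "", "system"))) {
    rs <- Filter(function(r) r$system == sys, conv)
    quads <- vapply(rs, `[[`, "", "quadrant")
    tab <- sort(table(quads), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      ties <- c(ties, sys)   # tied mode: flag, make no outlier call
      next
    }
    modal <- names(tab)[1]
    for (r in rs) if (r$quadrant != modal)
      outliers <- rbind(outliers, data.frame(
        system = sys, member = r$member, quadrant = r$quadrant,
        modal_quadrant = modal, stringsAsFactors = FALSE))
  }
  list(outliers = outliers, mode_ties = ties)
}

#' Quadrant occupancy summary
#'
#' Counts converged records per (system, quadrant) cell, tallying
#' boundary-flagged members separately; counts over a system sum to its
#' number of converged records.
#'
#' @param records List of `meci_record`s (as produced by [run_study()]).
#' @return Data frame (system, quadrant, n, n_boundary); a zero-row frame
#'   with these columns when no record converged.
#' @export
quadrant_summary <- function(records) {
  if (!length(records)) stop("empty record list")
  conv <- Filter(function(r) r$converged, records)
  empty <- data.frame(system = character(), quadrant = character(),
                      n = integer(), n_boundary = integer(),
                      stringsAsFactors = FALSE)
  if (!length(conv)) return(empty)
  df <- do.call(rbind, lapply(conv, function(r) data.frame(
    system = r$system, quadrant = r$quadrant,
    boundary = length(r$class$boundary_flags) > 0L,
    stringsAsFactors = FALSE)))
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(df)),
                                n_boundary = df$boundary),
                          by = list(system = df$system,
                                    quadrant = df$quadrant),
                          FUN = sum)
  agg <- agg[order(agg$system, agg$quadrant), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

write_quadrant_csv <- function(qt, path) {
  lines <- c("system,quadrant,n,n_boundary",
             if (nrow(qt)) sprintf("%s,%s,%d,%d", qt$system, qt$quadrant,
                                   qt$n, qt$n_boundary))
  writeLines(lines, path)
  invisible(path)
}

#' Export P-B scatter data as CSV
#'
#' One row per record with the full topography and classification fields,
#' in stable column order and full precision (round-trips to 12+
#' significant digits); the plot-ready data behind a P-B quadrant figure.
#'
#' @param records List of `meci_record`s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_scatter <- function(records, path) {
  header <- paste("system,member,converged,pitch,asymmetry,tilt_magnitude",
                  "tilt_heading,p_value,b_value,vertical,lateral,flags",
                  sep = ",")
  num <- function(x) sprintf("%.17g", x)
  rows <- vapply(records, function(r) {
    if (r$converged) {
      fl <- c(r$topography$flags, r$class$boundary_flags)
      paste(r$system, r$member, "TRUE",
            num(r$topography$pitch), num(r$topography$asymmetry),
            num(r$topography$tilt_magnitude), num(r$topography$tilt_heading),
            num(r$topography$p_value), num(r$topography$b_value),
            r$class$vertical, r$class$lateral,
            paste(fl, collapse = ";"), sep = ",")
    } else {
      paste(r$system, r$member, "FALSE", "", "", "", "", "", "", "", "", "",
            sep = ",")
    }
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read back a scatter CSV
#'
#' @param path CSV written by [export_scatter()].
#' @return Data frame with the scatter columns.
#' @export
read_scatter <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(system = "character",
                                 member = "character"))
}

export_records_json <- function(records, path) {
  objs <- lapply(records, function(r) {
    o <- list(format = "citopo-record/1", system = r$system,
              member = r$member, converged = r$converged,
              q_star = r$q_star, gap = r$gap,
              mean_energy = r$mean_energy,
              n_iterations = r$n_iterations, provenance = r$provenance)
    if (r$converged) {
      o$topography <- unclass(r$topography)
      o$class <- unclass(r$class)
    }
    o
  })
  writeLines(jsonlite::toJSON(objs, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
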