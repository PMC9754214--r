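# Batch orchestration: QC -> correct -> smooth -> normalize -> traits ->
# classify over directories of key-point files, descriptive statistics, and
# the raw-versus-smoothed parameter-recovery harness.

#' Process one sample into a trait-table row
#'
#' Wraps [fit_midrib()]; any stage error yields a row with `valid = FALSE`
#' and an error message instead of an exception, so batches never abort on a
#' single bad sample.
#'
#' @param sample A `midrib_sample`.
#' @param control A [midrib_control()] list.
#' @param smooth Logical; `FALSE` computes raw (unsmoothed) traits.
#' @return A one-row data.frame with the columns of [trait_columns()] plus
#'   `error`.
#' @export
process_sample <- function(sample, control = midrib_control(), smooth = TRUE) {
  fit <- tryCatch(fit_midrib(sample, control = control, smooth = smooth),
                  error = function(e) e)
  row <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(trait_names())), trait_names())))
  row <- cbind(data.frame(sample_id = sample$sample_id,
                          stringsAsFactors = FALSE), row)
  row$base_type <- NA_character_
  row$deflected <- NA
  row$valid <- FALSE
  row$n_iterations <- NA_integer_
  row$converged <- NA
  row$error <- NA_character_
  if (inherits(fit, "error")) {
    row$error <- conditionMessage(fit)
    return(row)
  }
  if (!fit$valid) {
    row$error <- fit$error
    return(row)
  }
  for (nm in trait_names()) row[[nm]] <- fit$traits[[nm]]
  row$base_type <- fit$class_$base_type
  row$deflected <- fit$class_$deflected
  row$valid <- TRUE
  row$n_iterations <- as.integer(fit$report$n_iterations)
  row$converged <- isTRUE(fit$report$converged)
  row
}

#' Discover and process every sample pair in a directory
#'
#' Samples follow the `<id>.stalk.csv` / `<id>.midrib.csv` convention;
#' unpaired files are skipped with a warning. Output rows are ordered by
#' sample id, so re-runs are byte-identical.
#'
#' @param input_dir Directory of key-point files.
#' @param control A [midrib_control()] list.
#' @param out Optional path for the trait CSV ([write_traits()]).
#' @param json_dir Optional directory for per-sample curve JSON exports.
#' @param smooth Logical; `FALSE` for raw (unsmoothed) traits.
#' @return The trait data.frame, invisibly when `out` is given.
#' @export
process_batch <- function(input_dir, control = midrib_control(), out = NULL,
                          json_dir = NULL, smooth = TRUE) {
  if (!dir.exists(input_dir)) stop("process_batch: no such directory: ", input_dir)
  stalks <- sort(list.files(input_dir, pattern = "\\.stalk\\.csv$"))
  ids <- sub("\\.stalk\\.csv$", "", stalks)
  if (!length(ids)) stop("process_batch: no '<id>.stalk.csv' files in ", input_dir)
  rows <- list()
  for (id in ids) {
    mp <- file.path(input_dir, paste0(id, ".midrib.csv"))
    if (!file.exists(mp)) {
      warning("process_batch: skipping unpaired sample '", id, "'")
      next
    }
    sample <- read_sample(file.path(input_dir, paste0(id, ".stalk.csv")), mp)
    row <- process_sample(sample, control, smooth = smooth)
    rows[[length(rows) + 1L]] <- row
    if (!is.null(json_dir) && row$valid) {
      if (!dir.exists(json_dir)) dir.create(json_dir, recursive = TRUE)
      fit <- fit_midrib(sample, control = control, smooth = smooth)
      write_curve_json(sample$sample_id, sample$midrib, fit$key_points,
                       fit$dense, fit$report,
                       file.path(json_dir, paste0(id, ".curve.json")))
    }
  }
  if (!length(rows)) stop("process_batch: no processable sample pairs found")
  df <- do.call(rbind, rows)
  df <- df[order(df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("processed %d samples (%d valid, %d rejected)",
                  nrow(df), sum(df$valid), sum(!df$valid)))
  if (!is.null(out)) {
    write_traits(df, out)
    return(invisible(df))
  }
  df
}

#' Descriptive statistics of a trait table
#'
#' Per-trait Mean, Min, Max, Range, Var (n-1 denominator), SD and CV
#' (SD/Mean), over valid rows, plus the pairwise-complete Pearson
#' correlation matrix.
#'
#' @param traits A trait data.frame (as from [process_batch()]).
#' @return A list with `summary` (data.frame, one row per trait) and
#'   `correlation` (15 x 15 matrix).
#' @export
summarize_traits <- function(traits) {
  if ("valid" %in% names(traits)) {
    traits <- traits[!is.na(traits$valid) & traits$valid, , drop = FALSE]
  }
  if (nrow(traits) < 2) stop("summarize_traits: need at least 2 valid rows")
  tn <- intersect(trait_names(), names(traits))
  rows <- lapply(tn, function(nm) {
    v <- traits[[nm]]
    v <- v[is.finite(v)]
    m <- mean(v); s <- stats::sd(v)
    data.frame(Trait = nm, Mean = m, Min = min(v), Max = max(v),
               Range = max(v) - min(v), Var = stats::var(v), SD = s,
               CV = if (abs(m) > 1e-12) s / m else 0,
               stringsAsFactors = FALSE)
  })
  corr <- suppressWarnings(stats::cor(as.matrix(traits[, tn]),
                                      use = "pairwise.complete.obs"))
  diag(corr) <- 1  # constant columns still correlate perfectly with themselves
  list(summary = do.call(rbind, rows), correlation = corr)
}

#' Compare raw and smoothed trait estimates against ground truth
#'
#' For each trait, the root-mean-square error and squared Pearson
#' correlation of both estimate sets against the truth table (matched on
#' `sample_id`), and the RMSE reduction fraction
#' `1 - RMSE_smoothed / RMSE_raw`.
#'
#' @param truth Truth table (sample_id + trait columns).
#' @param raw Trait table from unsmoothed key points.
#' @param smoothed Trait table from the full pipeline.
#' @param traits Traits to evaluate; defaults to all fifteen.
#' @return A data.frame: trait, n, rmse_raw, rmse_smoothed, reduction,
#'   r2_raw, r2_smoothed.
#' @export
validate_traits <- function(truth, raw, smoothed, traits = trait_names()) {
  ids <- Reduce(intersect, list(truth$sample_id, raw$sample_id,
                                smoothed$sample_id))
  if (!length(ids)) stop("validate_traits: no overlapping sample ids")
  t_ <- truth[match(ids, truth$sample_id), , drop = FALSE]
  r_ <- raw[match(ids, raw$sample_id), , drop = FALSE]
  s_ <- smoothed[match(ids, smoothed$sample_id), , drop = FALSE]
  rows <- lapply(traits, function(nm) {
    ok <- is.finite(t_[[nm]]) & is.finite(r_[[nm]]) & is.finite(s_[[nm]])
    tv <- t_[[nm]][ok]; rv <- r_[[nm]][ok]; sv <- s_[[nm]][ok]
    rmse <- function(a, b) sqrt(mean((a - b)^2))
    r2 <- function(a, b) {
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
      stats::cor(a, b)^2
    }
    rr <- rmse(rv, tv); rs <- rmse(sv, tv)
    data.frame(trait = nm, n = sum(ok), rmse_raw = rr, rmse_smoothed = rs,
               reduction = if (rr > 0) 1 - rs / rr else 0,
               r2_raw = r2(rv, tv), r2_smoothed = r2(sv, tv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic parameter-recovery benchmark
#'
#' Generates a seeded synthetic population, processes every sample twice
#' (raw key-point traits and fully smoothed traits) and validates both
#' against the noise-free ground truth — the package's analogue of a
#' smoothed-versus-raw accuracy evaluation against manual measurement.
#'
#' @param n Population size.
#' @param seed Integer seed.
#' @param noise A [midrib_noise()] spec.
#' @param control A [midrib_control()] list.
#' @return A list with `truth`, `raw`, `smoothed` (trait data.frames) and
#'   `validation` (from [validate_traits()]).
#' @export
run_recovery_benchmark <- function(n = 150, seed = 1,
                                   noise = midrib_noise(),
                                   control = midrib_control()) {
  pop <- generate_population(n, noise = noise, seed = seed, control = control)
  raw <- do.call(rbind, lapply(pop$samples, process_sample, control = control,
                               smooth = FALSE))
  smoothed <- do.call(rbind, lapply(pop$samples, process_sample,
                                    control = control, smooth = TRUE))
  list(truth = pop$truth, raw = raw, smoothed = smoothed,
       validation = validate_traits(pop$truth, raw, smoothed))
}
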