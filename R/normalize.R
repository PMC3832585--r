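#' Average per-field measurements to well level
#'
#' Morphometric and intensity totals are averaged per well as the arithmetic
#' mean over the imaged fields (6 by default in the screen design).
#'
#' @param fields data.frame with one row per (plate, well, field), carrying
#'   the identifier/annotation columns (`plate_id`, `well_id`, `role`,
#'   `gene`, `oligo`, `dose`, `replicate`) and the measurement columns
#'   `neurite_length`, `cell_body_area`, `marker_intensity`,
#'   `reporter_intensity`.
#' @return data.frame with one row per (plate, well) and per-channel means,
#'   plus `n_fields`.
#' @export
aggregate_wells <- function(fields) {
  if (!is.data.frame(fields) || nrow(fields) < 1L)
    stop("aggregate_wells(): 'fields' must contain at least one field", call. = FALSE)
  chans <- measurement_channels()
  miss <- setdiff(c("plate_id", "well_id", chans), names(fields))
  if (length(miss))
    stop("aggregate_wells(): missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(fields$plate_id, fields$well_id, sep = "\r")
  m <- rowsum(as.matrix(fields[chans]), key, reorder = FALSE)
  n <- as.vector(rowsum(rep(1, nrow(fields)), key, reorder = FALSE))
  first <- !duplicated(key)
  meta_cols <- intersect(c("plate_id", "well_id", "role", "gene", "oligo",
                           "dose", "replicate"), names(fields))
  wells <- fields[first, meta_cols, drop = FALSE]
  wells <- cbind(wells, as.data.frame(m / n), n_fields = n)
  rownames(wells) <- NULL
  wells
}

measurement_channels <- function() {
  c("neurite_length", "cell_body_area", "marker_intensity", "reporter_intensity")
}

#' Percent-of-control transformation
#'
#' Expresses a raw measurement on the plate's control scale:
#' `100 * (value - neg_mean) / (pos_mean - neg_mean)`, so the positive-control
#' mean maps to 100 and the negative-control mean to 0. Values are not
#' clipped. Marker-derived quantities (cell-body area, neurite length) are
#' normalized against the positive-control mean only (`neg_mean = 0`),
#' because undifferentiated negative controls carry no neuronal marker.
#'
#' @param value numeric vector of raw measurements.
#' @param pos_mean positive-control mean of the measurement.
#' @param neg_mean negative-control mean (default 0).
#' @return numeric vector in percent.
#' @export
to_percent <- function(value, pos_mean, neg_mean = 0) {
  if (!is.finite(pos_mean) || !is.finite(neg_mean) || pos_mean == neg_mean)
    stop("to_percent(): degenerate controls (positive and negative control means are equal)",
         call. = FALSE)
  100 * (value - neg_mean) / (pos_mean - neg_mean)
}

#' Ordinary least-squares control regression
#'
#' Fits the plate-wise regression line through the positive-control points
#' (vertical residuals), used as the reference for the regression-deviation
#' statistic.
#'
#' @param x,y percent coordinates of the plate's positive-control wells.
#' @return named numeric vector `c(m = slope, b = intercept)`.
#' @export
fit_control_regression <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("fit_control_regression(): need >= 3 (x, y) control points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fit_control_regression(): non-finite control coordinates", call. = FALSE)
  if (stats::var(x) == 0)
    stop("fit_control_regression(): degenerate controls (x values all equal)", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  c(m = unname(fit$coefficients[2]), b = unname(fit$coefficients[1]))
}

#' Regression-deviation statistic
#'
#' Signed orthogonal deviation of a point from the control regression line:
#' `d = (m * x - y + b) / sqrt(m^2 + 1)`. `|d|` equals the Euclidean
#' point-to-line distance; `d > 0` means the point lies below the line
#' (y smaller than predicted), i.e. reduced differentiation or outgrowth.
#'
#' @param x,y point coordinates in percent.
#' @param m,b slope and y-intercept of the control regression line.
#' @return numeric vector of deviations.
#' @export
regression_deviation <- function(x, y, m, b) {
  if (any(!is.finite(c(x, y, m, b))))
    stop("regression_deviation(): non-finite input", call. = FALSE)
  (m * x - y + b) / sqrt(m^2 + 1)
}

#' Per-plate control statistics
#'
#' For every plate, computes per-channel positive/negative-control means and
#' SDs, the percent-scale SD of the reporter signal (growth scale), and the
#' two control regressions with the SD of the positive-control deviations:
#' cell-body area (%) against reporter intensity (%) for differentiation,
#' and neurite length (%) against cell-body area (%) for outgrowth.
#'
#' @param wells well-level table from [aggregate_wells()] with a `role`
#'   column containing `positive_control` / `negative_control` entries.
#' @return data.frame with one row per plate.
#' @export
plate_control_stats <- function(wells) {
  stopifnot(is.data.frame(wells), "role" %in% names(wells))
  plates <- unique(wells$plate_id)
  rows <- lapply(plates, function(p) {
    w <- wells[wells$plate_id == p, , drop = FALSE]
    pos <- w[w$role == "positive_control", , drop = FALSE]
    neg <- w[w$role == "negative_control", , drop = FALSE]
    if (nrow(pos) < 3L)
      stop(sprintf("plate_control_stats(): plate '%s' has fewer than 3 positive-control wells", p),
           call. = FALSE)
    if (nrow(neg) < 1L)
      stop(sprintf("plate_control_stats(): plate '%s' has no negative-control wells", p),
           call. = FALSE)
    pm <- colMeans(pos[measurement_channels()])
    ps <- vapply(pos[measurement_channels()], stats::sd, numeric(1))
    nm <- colMeans(neg[measurement_channels()])
    if (ps["reporter_intensity"] == 0)
      stop(sprintf("plate_control_stats(): plate '%s' has zero positive-control reporter SD", p),
           call. = FALSE)
    rep_pct <- to_percent(pos$reporter_intensity, pm["reporter_intensity"],
                          nm["reporter_intensity"])
    area_pct <- to_percent(pos$cell_body_area, pm["cell_body_area"])
    len_pct <- to_percent(pos$neurite_length, pm["neurite_length"])
    reg_d <- fit_control_regression(rep_pct, area_pct)
    reg_o <- fit_control_regression(area_pct, len_pct)
    d_diff <- regression_deviation(rep_pct, area_pct, reg_d["m"], reg_d["b"])
    d_outg <- regression_deviation(area_pct, len_pct, reg_o["m"], reg_o["b"])
    data.frame(plate_id = p,
               replicate = if ("replicate" %in% names(w)) w$replicate[1] else NA_integer_,
               pos_mean_reporter = unname(pm["reporter_intensity"]),
               pos_mean_area = unname(pm["cell_body_area"]),
               pos_mean_length = unname(pm["neurite_length"]),
               pos_mean_marker = unname(pm["marker_intensity"]),
               neg_mean_reporter = unname(nm["reporter_intensity"]),
               mean_reporter_pct = mean(rep_pct),
               sd_reporter_pct = stats::sd(rep_pct),
               m_diff = unname(reg_d["m"]), b_diff = unname(reg_d["b"]),
               sd_d_diff = stats::sd(d_diff),
               m_outg = unname(reg_o["m"]), b_outg = unname(reg_o["b"]),
               sd_d_outg = stats::sd(d_outg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Growth score of a single well
#'
#' Overall growth of transfected precursors, measured as the
#' percent-transformed reporter (EGFP) intensity expressed in units of the
#' positive-control standard deviation: negative values mean reduced growth.
#'
#' @param reporter_intensity raw well-mean reporter intensity (vector).
#' @param stats one row of [plate_control_stats()] for the well's plate.
#' @return numeric score(s) in control-SD units.
#' @export
growth_score <- function(reporter_intensity, stats) {
  if (stats$sd_reporter_pct <= 0)
    stop("growth_score(): degenerate controls (zero reporter SD)", call. = FALSE)
  pct <- to_percent(reporter_intensity, stats$pos_mean_reporter, stats$neg_mean_reporter)
  (pct - stats$mean_reporter_pct) / stats$sd_reporter_pct
}

# per-well (x, y, d, score) rows for one measure on one plate
score_wells_one_plate <- function(w, st, measure) {
  if (measure == "growth") {
    x <- to_percent(w$reporter_intensity, st$pos_mean_reporter, st$neg_mean_reporter)
    y <- NA_real_
    d <- NA_real_
    score <- (x - st$mean_reporter_pct) / st$sd_reporter_pct
  } else if (measure == "differentiation") {
    x <- to_percent(w$reporter_intensity, st$pos_mean_reporter, st$neg_mean_reporter)
    y <- to_percent(w$cell_body_area, st$pos_mean_area)
    d <- regression_deviation(x, y, st$m_diff, st$b_diff)
    if (st$sd_d_diff <= 0)
      stop("phenotype_scores(): zero control deviation SD (differentiation)", call. = FALSE)
    score <- d / st$sd_d_diff
  } else {
    x <- to_percent(w$cell_body_area, st$pos_mean_area)
    y <- to_percent(w$neurite_length, st$pos_mean_length)
    d <- regression_deviation(x, y, st$m_outg, st$b_outg)
    if (st$sd_d_outg <= 0)
      stop("phenotype_scores(): zero control deviation SD (outgrowth)", call. = FALSE)
    score <- d / st$sd_d_outg
  }
  data.frame(w[intersect(c("plate_id", "well_id", "role", "gene", "oligo",
                           "dose", "replicate"), names(w))],
             measure = measure, x = x, y = y, d = d, score = score,
             stringsAsFactors = FALSE)
}

#' Per-well standardized scores
#'
#' Computes, for every well (controls included), the percent coordinates, the
#' regression deviation `d` and the standardized score for the requested
#' measures, against the well's own plate statistics. By construction the
#' positive-control standardized deviations on each plate have sample mean 0
#' and sample SD 1.
#'
#' @param wells well table from [aggregate_wells()].
#' @param stats per-plate statistics; computed from `wells` if `NULL`.
#' @param measures subset of `c("growth", "differentiation", "outgrowth")`.
#' @return long data.frame with one row per well and measure.
#' @export
score_wells <- function(wells, stats = NULL,
                        measures = c("growth", "differentiation", "outgrowth")) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(stats)) stats <- plate_control_stats(wells)
  out <- lapply(unique(wells$plate_id), function(p) {
    st <- stats[stats$plate_id == p, , drop = FALSE]
    if (nrow(st) != 1L)
      stop(sprintf("score_wells(): no control statistics for plate '%s'", p), call. = FALSE)
    w <- wells[wells$plate_id == p, , drop = FALSE]
    do.call(rbind, lapply(measures, function(m) score_wells_one_plate(w, st, m)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Phenotype scores per gene, oligo, dose and measure
#'
#' Standardizes every treatment well against its own replicate plate's
#' control statistics and combines the replicate plates into mean +/- SEM
#' (SEM = SD of the replicate scores / sqrt(n)).
#'
#' @param wells well table from [aggregate_wells()], or a `synthetic_screen`.
#' @param stats optional per-plate statistics (computed if `NULL`).
#' @param measures measures to score.
#' @param per_field if `TRUE`, deviations are computed per field first and
#'   averaged within the well, instead of from the well-mean measurements
#'   (the default); requires a field-level table with a `field` column.
#' @param fields field-level table, required when `per_field = TRUE`.
#' @param audit if `TRUE`, append the per-replicate scores as a
#'   comma-separated audit column.
#' @return data.frame with one row per (gene, oligo, dose, measure):
#'   replicate count `n`, `mean`, `sem`.
#' @export
phenotype_scores <- function(wells, stats = NULL,
                             measures = c("growth", "differentiation", "outgrowth"),
                             per_field = FALSE, fields = NULL, audit = FALSE) {
  if (inherits(wells, "synthetic_screen")) {
    fields <- wells$fields
    wells <- aggregate_wells(fields)
  }
  measures <- match.arg(measures, several.ok = TRUE)
  if (per_field) {
    if (is.null(fields))
      stop("phenotype_scores(): per_field = TRUE needs the field-level table", call. = FALSE)
    obs <- fields
    obs$well_of <- obs$well_id
    obs$well_id <- paste(obs$well_id, obs$field, sep = ".")
    if (is.null(stats)) stats <- plate_control_stats(wells)
    sw <- score_wells(obs, stats, measures)
    sw$well_id <- sub("\\.[0-9]+$", "", sw$well_id)
    agg <- stats::aggregate(score ~ plate_id + well_id + role + gene + oligo +
                              dose + replicate + measure, data = sw, FUN = mean)
    sw <- agg
  } else {
    sw <- score_wells(wells, stats, measures)
  }
  tr <- sw[sw$role == "treatment", , drop = FALSE]
  if (nrow(tr) == 0L)
    stop("phenotype_scores(): no treatment wells found", call. = FALSE)
  key <- paste(tr$gene, tr$oligo, tr$dose, tr$measure, sep = "\r")
  first <- !duplicated(key)
  n <- as.vector(rowsum(rep(1, nrow(tr)), key, reorder = FALSE))
  mu <- as.vector(rowsum(tr$score, key, reorder = FALSE)) / n
  # two-pass (centred) variance for numerical stability
  resid2 <- (tr$score - mu[match(key, key[first])])^2
  ss <- as.vector(rowsum(resid2, key, reorder = FALSE))
  sem_ <- ifelse(n > 1, sqrt(ss / (n - 1)) / sqrt(n), NA_real_)
  out <- data.frame(tr[first, c("gene", "oligo", "dose", "measure")],
                    n = n, mean = mu, sem = sem_, stringsAsFactors = FALSE)
  if (audit) {
    out$replicate_scores <- vapply(split(signif(tr$score, 8), factor(key, levels = key[first])),
                                   paste, character(1), collapse = ",")
  }
  rownames(out) <- NULL
  out[order(out$measure, out$gene, out$oligo, out$dose), ]
}
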