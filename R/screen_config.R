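#' Define the gene/oligo effect table of a synthetic screen
#'
#' Each row describes one treatment series: a gene targeted either by a pooled
#' mixture of siRNA oligonucleotides (`oligo = "pool"`, the primary-screen
#' situation) or by a single oligo (secondary-screen situation). The injected
#' effect is expressed in units of the positive-control standard deviation of
#' the corresponding standardized measure at the maximal dose.
#'
#' @param gene character vector of gene identifiers.
#' @param class effect class per gene, one of `"null"`, `"proliferation"`,
#'   `"differentiation"`, `"outgrowth"`. Recycled if length 1.
#' @param size signed effect size in control-SD units at the maximal dose.
#'   The sign follows the standardized scores: for growth, negative means
#'   reduced precursor growth; for differentiation and outgrowth, positive
#'   means a decrease of the measure (shorter neurites, fewer neurons).
#'   Recycled if length 1.
#' @param oligo oligo identifier per row (default `"pool"`). A gene may appear
#'   with several oligos to emulate a secondary screen.
#' @return data.frame with columns `gene`, `oligo`, `class`, `size`. Optional
#'   numeric columns `growth`, `differentiation`, `outgrowth` may be added to
#'   the returned table to co-inject additional shifts (in control-SD units
#'   at the maximal dose) on top of the class-based effect, e.g. an outgrowth
#'   gene whose knockdown also impairs precursor growth.
#' @examples
#' screen_targets(c("Mapre2", "Dync1h1", "ctrlA"),
#'                class = c("outgrowth", "outgrowth", "null"),
#'                size  = c(-4, 6, 0))
#' @export
screen_targets <- function(gene, class = "null", size = 0, oligo = "pool") {
  n <- length(gene)
  df <- data.frame(gene = as.character(gene),
                   oligo = rep_len(as.character(oligo), n),
                   class = rep_len(as.character(class), n),
                   size = rep_len(as.numeric(size), n),
                   stringsAsFactors = FALSE)
  validate_targets(df)
  df
}

#' Effect table with all-null genes
#'
#' @param n_genes number of genes.
#' @param prefix gene name prefix.
#' @return data.frame as [screen_targets()].
#' @export
null_targets <- function(n_genes, prefix = "gene") {
  screen_targets(sprintf("%s%04d", prefix, seq_len(n_genes)))
}

validate_targets <- function(targets) {
  if (!is.data.frame(targets) || nrow(targets) < 1L)
    config_error("targets", "must be a non-empty data.frame")
  need <- c("gene", "oligo", "class", "size")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    config_error("targets", paste("is missing columns:", paste(miss, collapse = ", ")))
  classes <- c("null", "proliferation", "differentiation", "outgrowth")
  bad <- setdiff(unique(targets$class), classes)
  if (length(bad))
    config_error("targets$class", paste("contains unknown classes:", paste(bad, collapse = ", ")))
  if (any(!is.finite(targets$size)))
    config_error("targets$size", "must be finite")
  # optional per-axis shift columns, added on top of the class-based effect
  for (ax in c("growth", "differentiation", "outgrowth")) {
    if (ax %in% names(targets) && any(!is.finite(targets[[ax]])))
      config_error(paste0("targets$", ax), "must be finite")
  }
  if (anyDuplicated(targets[c("gene", "oligo")]))
    config_error("targets", "has duplicated (gene, oligo) rows")
  invisible(targets)
}

#' Raw-signal anchors of the synthetic screen generator
#'
#' Per-field expectations for an unperturbed, fully differentiated
#' positive-control well. The defaults emulate roughly 1000 neurons spread
#' over 6 microscopic fields: about 167 neurons per field, each contributing
#' a soma of ~78 px and ~60 px of neurite.
#'
#' @param neurons_per_field expected neurons per field in positive controls.
#' @param soma_area_px mean soma area in pixels.
#' @param neurite_px mean neurite length per neuron in pixels.
#' @param reporter_per_neuron integrated transfection-reporter (EGFP) counts
#'   per neuron.
#' @param marker_per_area_px integrated neuronal-marker counts per pixel of
#'   cell-body area.
#' @param neg_reporter_frac negative-control reporter level as a fraction of
#'   the positive-control level. Undifferentiated wells keep dividing and
#'   dilute the reporter plasmid, so the fraction is below 1; this keeps the
#'   percent scale oriented so that negative growth scores mean reduced
#'   growth.
#' @return named list of anchors.
#' @export
screen_anchors <- function(neurons_per_field = 1000 / 6,
                           soma_area_px = 78,
                           neurite_px = 60,
                           reporter_per_neuron = 5000,
                           marker_per_area_px = 12,
                           neg_reporter_frac = 0.30) {
  a <- list(neurons_per_field = check_fraction(neurons_per_field, "neurons_per_field", 1e-6),
            soma_area_px = check_fraction(soma_area_px, "soma_area_px", 1e-6),
            neurite_px = check_fraction(neurite_px, "neurite_px", 1e-6),
            reporter_per_neuron = check_fraction(reporter_per_neuron, "reporter_per_neuron", 1e-6),
            marker_per_area_px = check_fraction(marker_per_area_px, "marker_per_area_px", 1e-6),
            neg_reporter_frac = check_fraction(neg_reporter_frac, "neg_reporter_frac", 0, 0.95))
  structure(a, class = "screen_anchors")
}

#' Configure a synthetic 384-well siRNA screen
#'
#' Describes the study design the generator emulates: triplicate 384-well
#' plates carrying 20 positive-control wells (differentiated, no siRNA),
#' 20 negative-control wells (not differentiated) and 4-point siRNA dose
#' titrations (0.5-4 pmol) of the treatment genes, with 6 imaged fields per
#' well.
#'
#' Two distinct sources of variation are configured separately.
#' `control_scatter` sets the magnitude of the deterministic well-to-well
#' spread of the control wells (growth, differentiation and outgrowth
#' components); it defines the plate control standard deviations that the
#' whole analysis is expressed in, and is therefore part of the design, not
#' of the noise. `noise_cv` is the stochastic per-field measurement noise
#' (multiplicative log-normal around the well mean); setting it to 0 yields a
#' fully deterministic screen.
#'
#' @param targets effect table from [screen_targets()] / [null_targets()].
#' @param doses strictly increasing positive siRNA doses in pmol.
#' @param n_replicate_plates number of replicate plates (screen repetitions).
#' @param fields_per_well number of microscopic fields imaged per well.
#' @param n_pos_controls,n_neg_controls control wells per plate.
#' @param noise_cv per-field measurement coefficient of variation.
#' @param control_scatter named list with elements `growth`,
#'   `differentiation`, `outgrowth`: relative magnitudes of the deterministic
#'   control-well spread along each axis.
#' @param anchors raw-signal anchors from [screen_anchors()].
#' @param dose_response `"linear"` (effect proportional to dose/max dose) or
#'   `"constant"` (full effect at all doses).
#' @param plate_size wells per plate.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class `screen_config`.
#' @examples
#' cfg <- screen_config(null_targets(10), doses = 4, seed = 1)
#' cfg
#' @export
screen_config <- function(targets,
                          doses = c(0.5, 1, 2, 4),
                          n_replicate_plates = 3,
                          fields_per_well = 6,
                          n_pos_controls = 20,
                          n_neg_controls = 20,
                          noise_cv = 0.02,
                          control_scatter = list(growth = 0.10,
                                                 differentiation = 0.08,
                                                 outgrowth = 0.08),
                          anchors = screen_anchors(),
                          dose_response = c("linear", "constant"),
                          plate_size = 384,
                          seed = 1) {
  validate_targets(targets)
  if (!is.numeric(doses) || length(doses) < 1L || any(!is.finite(doses)) ||
      any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    config_error("doses", "must be strictly increasing and positive")
  n_replicate_plates <- check_count(n_replicate_plates, "n_replicate_plates")
  fields_per_well <- check_count(fields_per_well, "fields_per_well")
  n_pos_controls <- check_count(n_pos_controls, "n_pos_controls", min = 8L)
  if (n_pos_controls %% 4L != 0L)
    config_error("n_pos_controls", "must be a multiple of 4 (controls are laid out in quadruples)")
  n_neg_controls <- check_count(n_neg_controls, "n_neg_controls", min = 2L)
  noise_cv <- check_fraction(noise_cv, "noise_cv", 0, 1)
  plate_size <- check_count(plate_size, "plate_size", min = 8L)
  for (nm in c("growth", "differentiation", "outgrowth")) {
    if (is.null(control_scatter[[nm]]))
      config_error("control_scatter", paste("is missing element", nm))
    control_scatter[[nm]] <- check_fraction(control_scatter[[nm]],
                                            paste0("control_scatter$", nm), 1e-6, 0.5)
  }
  if (!inherits(anchors, "screen_anchors"))
    anchors <- do.call(screen_anchors, anchors)
  dose_response <- match.arg(dose_response)
  seed <- check_count(seed, "seed", min = 0L)
  n_treat <- plate_size - n_pos_controls - n_neg_controls
  if (n_treat < length(doses))
    config_error("plate_size", "leaves no room for treatment wells after controls")
  cfg <- list(targets = targets, doses = as.numeric(doses),
              n_replicate_plates = n_replicate_plates,
              fields_per_well = fields_per_well,
              n_pos_controls = n_pos_controls, n_neg_controls = n_neg_controls,
              noise_cv = noise_cv, control_scatter = control_scatter,
              anchors = anchors, dose_response = dose_response,
              plate_size = plate_size, seed = seed)
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Synthetic screen configuration\n")
  cat(sprintf("  %d treatment series (%d genes), doses %s pmol\n",
              nrow(x$targets), length(unique(x$targets$gene)),
              paste(x$doses, collapse = "/")))
  cat(sprintf("  %d replicate plates of %d wells (%d+ / %d- controls), %d fields/well\n",
              x$n_replicate_plates, x$plate_size,
              x$n_pos_controls, x$n_neg_controls, x$fields_per_well))
  cat(sprintf("  field noise CV %.3g, seed %d\n", x$noise_cv, x$seed))
  invisible(x)
}

#' Read or write a screen configuration as YAML
#'
#' The effect table is stored inline as a list of rows, so a configuration
#' file fully determines a screen.
#'
#' @param path file path.
#' @param config a `screen_config`.
#' @return [read_screen_config()] returns a `screen_config`.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$targets)) config_error("targets", "is missing from the config file")
  tg <- do.call(rbind, lapply(raw$targets, function(r)
    data.frame(gene = r$gene,
               oligo = if (is.null(r$oligo)) "pool" else r$oligo,
               class = if (is.null(r$class)) "null" else r$class,
               size = if (is.null(r$size)) 0 else as.numeric(r$size),
               stringsAsFactors = FALSE)))
  raw$targets <- tg
  if (!is.null(raw$anchors)) raw$anchors <- do.call(screen_anchors, raw$anchors)
  do.call(screen_config, raw)
}

#' @rdname read_screen_config
#' @export
write_screen_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  out <- unclass(config)
  out$anchors <- unclass(out$anchors)
  out$targets <- lapply(seq_len(nrow(config$targets)), function(i)
    as.list(config$targets[i, ]))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
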