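# Deterministic control-well spread patterns, sample mean 0 / sample SD 1.
# Positive-control wells come in quadruples sharing one growth level, with
# +/- differentiation and outgrowth contrasts inside each quadruple. The
# contrasts are thereby orthogonal to any function of the coarser levels, so
# the control regressions coincide exactly with the proportional-scaling
# lines and the three standardized measures decouple by construction.
control_patterns <- function(n) {
  stopifnot(n >= 8, n %% 4 == 0)
  ng <- n %/% 4
  c_raw <- rep(seq_len(ng), each = 4)
  u_raw <- rep(c(1, 1, -1, -1), ng)
  v_raw <- rep(c(1, -1, 1, -1), ng)
  cbind((c_raw - mean(c_raw)) / stats::sd(c_raw),
        u_raw / stats::sd(u_raw),
        v_raw / stats::sd(v_raw))
}

# linear pattern for negative-control wells (reporter spread only)
neg_pattern <- function(n) {
  z <- seq_len(n)
  (z - mean(z)) / stats::sd(z)
}

# Raw per-field channel anchors of an unperturbed positive-control well
anchor_values <- function(anchors) {
  A0 <- anchors$neurons_per_field * anchors$soma_area_px
  c(neurite_length = anchors$neurons_per_field * anchors$neurite_px,
    cell_body_area = A0,
    marker_intensity = anchors$marker_per_area_px * A0,
    reporter_intensity = anchors$neurons_per_field * anchors$reporter_per_neuron)
}

# Expected (noise-free) control well table of one plate
expected_control_wells <- function(config) {
  a <- anchor_values(config$anchors)
  cs <- config$control_scatter
  zp <- control_patterns(config$n_pos_controls)
  cgrow <- 1 + cs$growth * zp[, 1]
  u <- cs$differentiation * zp[, 2]
  v <- cs$outgrowth * zp[, 3]
  pos <- data.frame(
    role = "positive_control", gene = NA_character_, oligo = NA_character_,
    dose = NA_real_,
    neurite_length = a["neurite_length"] * cgrow * (1 + u) * (1 + v),
    cell_body_area = a["cell_body_area"] * cgrow * (1 + u),
    marker_intensity = a["marker_intensity"] * cgrow * (1 + u),
    reporter_intensity = a["reporter_intensity"] * cgrow,
    stringsAsFactors = FALSE)
  zn <- neg_pattern(config$n_neg_controls)
  neg <- data.frame(
    role = "negative_control", gene = NA_character_, oligo = NA_character_,
    dose = NA_real_,
    neurite_length = 0, cell_body_area = 0, marker_intensity = 0,
    reporter_intensity = a["reporter_intensity"] * config$anchors$neg_reporter_frac *
      (1 + cs$growth * zn),
    stringsAsFactors = FALSE)
  rbind(pos, neg)
}

# Control statistics of the expected (noise-free) plate, computed with the
# same normalization code that analyzes real plates
expected_plate_stats <- function(config) {
  ctrl <- expected_control_wells(config)
  ctrl$plate_id <- "expected"
  ctrl$well_id <- sprintf("C%03d", seq_len(nrow(ctrl)))
  plate_control_stats(ctrl)
}

# Invert the normalization chain: expected raw channel values of a treatment
# well with target standardized shifts (growth g, differentiation sdiff,
# outgrowth soutg), all vectors over treatment slots
place_treatments <- function(g, sdiff, soutg, st, anchors) {
  a <- anchor_values(anchors)
  target_rep_pct <- st$mean_reporter_pct + g * st$sd_reporter_pct
  R <- st$neg_mean_reporter +
    target_rep_pct / 100 * (st$pos_mean_reporter - st$neg_mean_reporter)
  phi <- R / a["reporter_intensity"]
  A <- phi * a["cell_body_area"]
  L <- phi * a["neurite_length"]
  M <- phi * a["marker_intensity"]
  # differentiation target: place the cell-body area at the prescribed
  # deviation from the differentiation control regression; neurite length and
  # marker scale along (same neurons, same mean neurite length)
  adj <- sdiff != 0
  if (any(adj)) {
    x <- target_rep_pct[adj]
    y <- st$m_diff * x + st$b_diff - sdiff[adj] * st$sd_d_diff * sqrt(st$m_diff^2 + 1)
    A_t <- pmax(y, 1e-9) / 100 * st$pos_mean_area
    psi <- A_t / A[adj]
    A[adj] <- A_t
    L[adj] <- L[adj] * psi
    M[adj] <- M[adj] * psi
  }
  # outgrowth target: place neurite length at the prescribed deviation from
  # the outgrowth control regression, given the well's area coordinate
  adj <- soutg != 0
  if (any(adj)) {
    x <- 100 * A[adj] / st$pos_mean_area
    y <- st$m_outg * x + st$b_outg - soutg[adj] * st$sd_d_outg * sqrt(st$m_outg^2 + 1)
    L[adj] <- pmax(y, 1e-9) / 100 * st$pos_mean_length
  }
  data.frame(neurite_length = unname(L), cell_body_area = unname(A),
             marker_intensity = unname(M), reporter_intensity = unname(R))
}

#' Generate a synthetic siRNA screen with known ground truth
#'
#' Builds the full field-level measurement table of a multi-plate, replicated
#' 384-well screen. Control wells carry the deterministic spread configured
#' in the design; treatment wells are placed by inverting the normalization
#' chain against the noise-free control statistics, so that the standardized
#' phenotype scores recovered downstream equal the injected effect sizes
#' (exactly at zero noise CV, in expectation otherwise). Per-field values are
#' then drawn from a multiplicative log-normal noise model around the well
#' mean.
#'
#' @param config a [screen_config()].
#' @return object of class `synthetic_screen`: a list with
#'   \describe{
#'     \item{fields}{data.frame, one row per (plate, well, field).}
#'     \item{wells_expected}{noise-free expected well table.}
#'     \item{truth}{per (gene, oligo, dose) injected standardized shifts and
#'       expected raw channel values; never re-derived from the data.}
#'     \item{control_stats_expected}{noise-free plate control statistics used
#'       for effect placement.}
#'     \item{config}{the configuration.}
#'   }
#' @examples
#' cfg <- screen_config(screen_targets(c("g1", "g2"), class = c("outgrowth", "null"),
#'                                     size = c(-5, 0)),
#'                      doses = 4, noise_cv = 0, seed = 7)
#' scr <- generate_screen(cfg)
#' head(scr$fields)
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  tg <- config$targets
  doses <- config$doses
  n_doses <- length(doses)
  n_slots <- nrow(tg) * n_doses
  slot <- data.frame(gene = rep(tg$gene, each = n_doses),
                     oligo = rep(tg$oligo, each = n_doses),
                     class = rep(tg$class, each = n_doses),
                     size = rep(tg$size, each = n_doses),
                     dose = rep(doses, times = nrow(tg)),
                     stringsAsFactors = FALSE)
  f <- if (config$dose_response == "linear") slot$dose / max(doses) else rep(1, n_slots)
  extra <- function(ax) if (ax %in% names(tg)) rep(tg[[ax]], each = n_doses) else 0
  g <- (ifelse(slot$class == "proliferation", slot$size, 0) + extra("growth")) * f
  sdiff <- (ifelse(slot$class == "differentiation", slot$size, 0) +
              extra("differentiation")) * f
  soutg <- (ifelse(slot$class == "outgrowth", slot$size, 0) + extra("outgrowth")) * f

  st <- expected_plate_stats(config)
  treat <- place_treatments(g, sdiff, soutg, st, config$anchors)
  ctrl <- expected_control_wells(config)

  truth <- data.frame(slot[c("gene", "oligo", "class", "dose")],
                      true_growth = g, true_differentiation = sdiff,
                      true_outgrowth = soutg,
                      expected_neurite_length = treat$neurite_length,
                      expected_cell_body_area = treat$cell_body_area,
                      expected_marker_intensity = treat$marker_intensity,
                      expected_reporter_intensity = treat$reporter_intensity,
                      stringsAsFactors = FALSE)

  # plate layout: controls occupy the first wells, treatment slots fill the
  # rest in order; a screen larger than one plate spans several plate blocks,
  # each with its own full set of controls
  n_ctrl <- config$n_pos_controls + config$n_neg_controls
  per_plate <- config$plate_size - n_ctrl
  n_blocks <- ceiling(n_slots / per_plate)
  wn <- well_names(config$plate_size)
  chans <- measurement_channels()

  block_wells <- lapply(seq_len(n_blocks), function(b) {
    idx <- seq((b - 1) * per_plate + 1, min(b * per_plate, n_slots))
    tw <- data.frame(role = "treatment", gene = slot$gene[idx],
                     oligo = slot$oligo[idx], dose = slot$dose[idx],
                     treat[idx, chans, drop = FALSE],
                     stringsAsFactors = FALSE)
    w <- rbind(ctrl[c("role", "gene", "oligo", "dose", chans)],
               tw[c("role", "gene", "oligo", "dose", chans)])
    w$well_id <- wn[seq_len(nrow(w))]
    w$block <- b
    w
  })
  one_rep <- do.call(rbind, block_wells)

  reps <- do.call(rbind, lapply(seq_len(config$n_replicate_plates), function(r) {
    w <- one_rep
    w$replicate <- r
    w$plate_id <- sprintf("P%02d_r%d", w$block, r)
    w
  }))
  reps$block <- NULL
  ord <- c("plate_id", "replicate", "well_id", "role", "gene", "oligo", "dose", chans)
  reps <- reps[ord]

  fw <- config$fields_per_well
  fields <- reps[rep(seq_len(nrow(reps)), each = fw), , drop = FALSE]
  fields$field <- rep(seq_len(fw), times = nrow(reps))
  rownames(fields) <- NULL

  if (config$noise_cv > 0) {
    sigma <- sqrt(log(1 + config$noise_cv^2))
    fields[chans] <- with_seed(config$seed, {
      z <- matrix(stats::rnorm(nrow(fields) * length(chans)), ncol = length(chans))
      as.matrix(fields[chans]) * exp(sigma * z - sigma^2 / 2)
    })
  }
  fields <- fields[c("plate_id", "replicate", "well_id", "field", "role",
                     "gene", "oligo", "dose", chans)]

  structure(list(fields = fields, wells_expected = reps, truth = truth,
                 control_stats_expected = st, config = config),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf("Synthetic screen: %d field rows, %d wells, %d plates, %d treatment series\n",
              nrow(x$fields), nrow(x$wells_expected),
              length(unique(x$fields$plate_id)), nrow(x$config$targets)))
  invisible(x)
}

#' Write a synthetic screen to CSV
#'
#' Emits `fields.csv` (one row per plate/well/field) and `truth.csv`
#' (injected ground truth) into a directory.
#'
#' @param screen a `synthetic_screen`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_screen_csv <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fields = file.path(dir, "fields.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(screen$fields, paths["fields"], row.names = FALSE)
  utils::write.csv(screen$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a field-level measurement table from CSV
#'
#' @param path CSV written by [write_screen_csv()] or produced externally
#'   with the same columns.
#' @return data.frame of field measurements.
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("plate_id", "well_id", "role", measurement_channels()), names(df))
  if (length(miss))
    stop("read_fields_csv(): missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  df
}
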