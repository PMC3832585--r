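# Render per-field channel images whose measured totals match the target
# per-field tabular values, then measure them back. Used by the image-level
# pipeline mode; the rendered scene is a simplified field (discs + straight
# neurites), not a photorealistic one.
render_and_measure_field <- function(targets, dim, anchors, soma_radius_measure,
                                     seed) {
  a0 <- anchors$soma_area_px
  A <- targets[["cell_body_area"]]; L <- targets[["neurite_length"]]
  M <- targets[["marker_intensity"]]; R <- targets[["reporter_intensity"]]
  k <- max(0L, as.integer(round(A / a0)))
  k_rep_only <- if (k == 0L && R > 0) max(1L, as.integer(round(R / anchors$reporter_per_neuron)))
                else 0L
  r_soma <- sqrt(a0 / pi)
  cells <- list()
  with_seed(seed, {
    n_draw <- max(k, k_rep_only)
    if (n_draw > 0L) {
      margin <- r_soma + (if (k > 0L) min(L / max(k, 1), dim[1] / 3) else 0) + 4
      pos <- cbind(stats::runif(n_draw, 1 + margin, dim[1] - margin),
                   stats::runif(n_draw, 1 + margin, dim[2] - margin))
      ang <- stats::runif(n_draw, 0, 2 * pi)
      for (i in seq_len(n_draw)) {
        neur <- list()
        if (k > 0L && L > 0) {
          len <- L / k
          dirv <- c(cos(ang[i]), sin(ang[i]))
          p0 <- pos[i, ] + (r_soma - 1) * dirv
          p1 <- pos[i, ] + (r_soma - 1 + len) * dirv
          neur <- list(rbind(p0, p1))
        }
        cells[[i]] <- field_cell(pos[i, ], r_soma, neur)
      }
    }
  })
  fi <- generate_field_images(cells, dim = dim, background = 100, noise_sd = 0,
                              marker_level = 1, reporter_level = 1,
                              nuclei_level = 500)
  npix <- fi$truth$total_intensity[["marker"]]  # marker mask pixel count (level 1)
  marker <- if (k > 0L && npix > 0) 100 + (fi$images$marker - 100) * (M / npix)
            else array(100, dim)
  reporter <- if (npix > 0 && R > 0) 100 + (fi$images$reporter - 100) * (R / npix)
              else array(100, dim)
  measure_field(marker, reporter, soma_radius = soma_radius_measure)
}

# Re-derive the field table of a synthetic screen through image rendering
# and morphometric measurement
measure_screen_images <- function(screen, dim = c(192, 192),
                                  soma_radius_measure = 4) {
  fields <- screen$fields
  chans <- measurement_channels()
  out <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    out[[i]] <- render_and_measure_field(
      as.list(fields[i, chans]), dim, screen$config$anchors,
      soma_radius_measure, seed = screen$config$seed + i)
  }
  meas <- do.call(rbind, out)
  fields[chans] <- meas[chans]
  fields
}

#' Percent-scale scatter of paired control-normalized measures
#'
#' Reproduces the classification view of the screen: control clouds
#' (positive controls black, negative controls red) and per-gene dose
#' trajectories as arrows pointing toward higher siRNA concentration, on the
#' percent scale of the plate controls.
#'
#' @param well_scores long table from [score_wells()].
#' @param measure `"differentiation"` (area% vs reporter%) or `"outgrowth"`
#'   (length% vs area%).
#' @return a ggplot object.
#' @export
plot_percent_scatter <- function(well_scores, measure = c("outgrowth", "differentiation")) {
  measure <- match.arg(measure)
  df <- well_scores[well_scores$measure == measure, , drop = FALSE]
  labs <- if (measure == "outgrowth")
    c("total neuronal cell-body area (%)", "total neurite length (%)")
  else c("EGFP reporter intensity (%)", "total neuronal cell-body area (%)")
  ctrl <- df[df$role != "treatment", , drop = FALSE]
  tr <- df[df$role == "treatment", , drop = FALSE]
  p <- ggplot2::ggplot(ctrl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role), size = 1.6) +
    ggplot2::scale_colour_manual(values = c(positive_control = "black",
                                            negative_control = "red3")) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(tr)) {
    agg <- stats::aggregate(cbind(x, y) ~ gene + dose, data = tr, FUN = mean)
    agg <- agg[order(agg$gene, agg$dose), ]
    if (length(unique(agg$dose)) > 1L) {
      p <- p + ggplot2::geom_path(
        data = agg, ggplot2::aes(group = .data$gene),
        arrow = grid::arrow(length = grid::unit(5, "pt"), type = "closed"),
        colour = "grey40", linewidth = 0.4)
    } else {
      p <- p + ggplot2::geom_point(data = agg, colour = "grey40", size = 1)
    }
  }
  p
}

#' Run the full screen analysis pipeline
#'
#' generate -> (render + quantify in image mode) -> normalize -> score ->
#' call -> report. All stage outputs are plain CSV so stages can be re-run
#' or inspected independently; a JSON manifest records the configuration
#' hash, seed and package version for provenance. Re-running with the same
#' configuration and seed reproduces byte-identical tables.
#'
#' @param config a [screen_config()] or the path to a YAML config file.
#' @param outdir output directory (created).
#' @param seed optional seed overriding the config seed.
#' @param mode `"tabular"` (field table straight from the generator) or
#'   `"images"` (per-field channel images are rendered and re-measured by
#'   the morphometry stage; intended for small demonstration screens).
#' @param dose_policy hit-calling dose policy, see [call_phenotypes()].
#' @param threshold hit threshold in control-SD units.
#' @param annotation optional functional-class annotation (data.frame or CSV
#'   path with columns `gene`, `class`) for the enrichment report.
#' @param make_plots write percent-scale scatter plots (PDF).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the stage outputs and file paths.
#' @export
run_pipeline <- function(config, outdir, seed = NULL,
                         mode = c("tabular", "images"),
                         dose_policy = c("max", "all"), threshold = 3,
                         annotation = NULL, make_plots = TRUE, quiet = FALSE) {
  mode <- match.arg(mode)
  dose_policy <- match.arg(dose_policy)
  t0 <- Sys.time()
  if (is.character(config)) config <- read_screen_config(config)
  stopifnot(inherits(config, "screen_config"))
  if (!is.null(seed)) config$seed <- check_count(seed, "seed", min = 0L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cfg_path <- file.path(outdir, "config.yml")
  write_screen_config(config, cfg_path)

  say("generate: %d treatment series x %d doses, %d replicate plates, seed %d",
      nrow(config$targets), length(config$doses), config$n_replicate_plates,
      config$seed)
  screen <- stage("generate", generate_screen(config))
  paths <- write_screen_csv(screen, outdir)

  fields <- screen$fields
  if (mode == "images") {
    say("quantify: rendering and measuring %d field images", nrow(fields))
    fields <- stage("quantify", measure_screen_images(screen))
    paths["fields_measured"] <- file.path(outdir, "fields_measured.csv")
    utils::write.csv(fields, paths["fields_measured"], row.names = FALSE)
  }

  say("normalize: aggregating %d field rows", nrow(fields))
  wells <- stage("normalize", aggregate_wells(fields))
  stats <- stage("normalize", plate_control_stats(wells))
  wscores <- stage("normalize", score_wells(wells, stats))
  scores <- stage("normalize", phenotype_scores(wells, stats, audit = TRUE))
  paths["wells"] <- file.path(outdir, "wells.csv")
  paths["control_stats"] <- file.path(outdir, "control_stats.csv")
  paths["scores"] <- file.path(outdir, "scores.csv")
  utils::write.csv(wells, paths["wells"], row.names = FALSE)
  utils::write.csv(stats, paths["control_stats"], row.names = FALSE)
  utils::write.csv(scores, paths["scores"], row.names = FALSE)

  n_rep <- config$n_replicate_plates
  say("call: threshold %g SD on the replicate mean (%d replicates); implied per-gene null false-positive rate %.3g%%",
      threshold, n_rep, 100 * 2 * stats::pnorm(-threshold * sqrt(n_rep)))
  calls <- stage("call", call_phenotypes(scores, threshold, dose_policy))
  paths["hits"] <- file.path(outdir, "hits.csv")
  utils::write.csv(calls, paths["hits"], row.names = FALSE)
  say("call: %d hit rows of %d scored (gene, measure) combinations",
      sum(calls$hit), nrow(calls))

  # secondary-screen reproduction, when the screen carries both pooled and
  # single-oligo series for the same genes
  repro <- NULL
  has_pool <- calls$oligo == "pool"
  single_genes <- unique(calls$gene[!has_pool])
  both <- intersect(unique(calls$gene[has_pool & calls$hit]), single_genes)
  if (length(both)) {
    prim <- calls[has_pool & calls$hit & calls$gene %in% both &
                    calls$measure != "growth", , drop = FALSE]
    if (nrow(prim)) {
      repro <- stage("call", do.call(rbind, lapply(split(prim, prim$measure), function(pm) {
        os <- scores[scores$oligo != "pool" & scores$gene %in% pm$gene &
                       scores$measure == pm$measure[1] &
                       scores$dose == max(scores$dose), , drop = FALSE]
        if (nrow(os)) secondary_reproduction(pm, os, threshold) else NULL
      })))
      if (!is.null(repro) && nrow(repro)) {
        paths["reproduction"] <- file.path(outdir, "reproduction.csv")
        utils::write.csv(repro, paths["reproduction"], row.names = FALSE)
        rs <- reproduction_summary(repro)
        say("reproduction: %d/%d (%.1f%%) by >=1 oligo, %d/%d (%.1f%%) by multiple",
            rs$n_any, rs$n_total, rs$pct_any, rs$n_multiple, rs$n_total, rs$pct_multiple)
      }
    }
  }

  enrich <- NULL
  if (!is.null(annotation)) {
    if (is.character(annotation))
      annotation <- utils::read.csv(annotation, stringsAsFactors = FALSE)
    hit_genes <- unique(calls$gene[calls$hit & !calls$excluded])
    enrich <- stage("report", class_enrichment(hit_genes, annotation))
    paths["enrichment"] <- file.path(outdir, "enrichment.csv")
    utils::write.csv(enrich, paths["enrichment"], row.names = FALSE)
  }

  if (make_plots) {
    for (m in c("differentiation", "outgrowth")) {
      p <- plot_percent_scatter(wscores, m)
      f <- file.path(outdir, sprintf("scatter_%s.pdf", m))
      ggplot2::ggsave(f, p, width = 5, height = 4)
      paths[paste0("plot_", m)] <- f
    }
  }

  manifest <- list(
    package = "neuritescreen",
    version = as.character(utils::packageVersion("neuritescreen")),
    seed = config$seed,
    mode = mode, dose_policy = dose_policy, threshold = threshold,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(vapply(paths, basename, character(1))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: outputs in %s", outdir)
  invisible(list(screen = screen, fields = fields, wells = wells,
                 control_stats = stats, scores = scores, calls = calls,
                 reproduction = repro, enrichment = enrich,
                 manifest = manifest, paths = paths, outdir = outdir))
}
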