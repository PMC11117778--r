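# Export and plotting: CSV edge lists, JSON summaries, legacy-VTK fields
# and polylines, base-graphics network/field plots.  Floats are written
# with 9 significant digits.

fmt9 <- function(x) formatC(x, digits = 9, format = "g")

#' Write a capillary network to a CSV edge list
#'
#' Columns x1, y1, x2, y2, order, step; [read_network_csv()] restores a
#' `capillary_network` whose metrics equal the original's.
#'
#' @param network A `capillary_network`.
#' @param path Output file.
#' @export
write_network_csv <- function(network, path) {
  seg <- network$segments
  out <- data.frame(x1 = fmt9(seg$x1), y1 = fmt9(seg$y1),
                    x2 = fmt9(seg$x2), y2 = fmt9(seg$y2),
                    order = seg$order, step = seg$step)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capillary network edge list written by [write_network_csv()]
#'
#' Branch points are recovered as segment start positions shared by more
#' than one outgoing segment.
#'
#' @param path CSV file.
#' @return A `capillary_network` (without tip bookkeeping).
#' @export
read_network_csv <- function(path) {
  seg <- utils::read.csv(path)
  starts <- paste(signif(seg$x1, 12), signif(seg$y1, 12))
  dup <- duplicated(starts)
  bp <- seg[starts %in% starts[dup] & !dup, c("x1", "y1", "step")]
  names(bp) <- c("x", "y", "step")
  structure(list(segments = seg, branch_points = bp,
                 tips = data.frame(), rng_seed = NA_integer_,
                 bounds = c(min(seg$x1, seg$x2), min(seg$y1, seg$y2),
                            max(seg$x1, seg$x2), max(seg$y1, seg$y2)),
                 iterations = max(seg$step), truncated = FALSE),
            class = "capillary_network")
}

#' Write a nodal/point scalar field as CSV (x, y, value columns)
#' @param coords m x 2 positions.
#' @param values Named list of numeric vectors (one column per field).
#' @param path Output file.
#' @export
write_field_csv <- function(coords, values, path) {
  df <- data.frame(x = fmt9(coords[, 1]), y = fmt9(coords[, 2]))
  for (nm in names(values)) df[[nm]] <- fmt9(values[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write point data as a legacy-VTK polydata file
#' @param coords m x 2 positions.
#' @param values Named list of per-point scalar vectors.
#' @param path Output `.vtk` file.
#' @export
write_vtk_points <- function(coords, values, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- nrow(coords)
  writeLines(c("# vtk DataFile Version 3.0", "angiomech field", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", m)), con)
  writeLines(paste(fmt9(coords[, 1]), fmt9(coords[, 2]), "0"), con)
  writeLines(sprintf("POINT_DATA %d", m), con)
  for (nm in names(values)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt9(values[[nm]]), con)
  }
  invisible(path)
}

#' Write a capillary network as VTK polylines
#' @param network A `capillary_network`.
#' @param path Output `.vtk` file.
#' @export
write_vtk_polylines <- function(network, path) {
  seg <- network$segments
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(seg)
  writeLines(c("# vtk DataFile Version 3.0", "capillary network", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", 2 * n)), con)
  writeLines(paste(fmt9(c(rbind(seg$x1, seg$x2))),
                   fmt9(c(rbind(seg$y1, seg$y2))), "0"), con)
  writeLines(sprintf("LINES %d %d", n, 3 * n), con)
  writeLines(paste(2, seq(0, by = 2, length.out = n),
                   seq(1, by = 2, length.out = n)), con)
  writeLines(c(sprintf("CELL_DATA %d", n), "SCALARS order int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(seg$order), con)
  invisible(path)
}

#' Summarise a network as JSON
#' @param network A `capillary_network`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @export
network_to_json <- function(network, path = NULL) {
  m <- network_metrics(network)
  obj <- list(rng_seed = network$rng_seed,
              iterations = network$iterations,
              total_length = m$total_length,
              n_branches = m$n_branches,
              n_segments = m$n_segments)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an experiment report (JSON + CSV + figures)
#' @param report An `experiment_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_seed,
                   file.path(out_dir, "per_seed_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(scenario = report$scenario, loading = report$loading,
         alpha = report$alpha, seeds = report$seeds,
         summary = lapply(report$summary, as.list)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  grDevices::png(file.path(out_dir, "networks.png"), 1200, 600, res = 120)
  graphics::par(mfrow = c(1, 2))
  plot_network(report$first_seed_networks$control, main = "control")
  plot_network(report$first_seed_networks$loaded,
               main = sprintf("%s (alpha = %g)", report$loading,
                              report$alpha))
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "percent_of_control.png"), 800, 600,
                 res = 120)
  s <- report$summary
  mid <- c(s$pct_length["mean"], s$pct_branches["mean"])
  sdv <- c(s$pct_length["sd"], s$pct_branches["sd"])
  bp <- graphics::barplot(mid, names.arg = c("vessel length", "branches"),
                          ylab = "% of control",
                          ylim = range(0, mid + sdv, mid - sdv))
  graphics::arrows(bp, mid - sdv, bp, mid + sdv, angle = 90, code = 3,
                   length = 0.06)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Plot a capillary network
#' @param network A `capillary_network`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_network <- function(network, ...) {
  b <- network$bounds
  graphics::plot(NA, xlim = b[c(1, 3)], ylim = b[c(2, 4)], asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  seg <- network$segments
  cols <- c("#7f0000", "#d7301f", "#fc8d59")
  graphics::segments(seg$x1, seg$y1, seg$x2, seg$y2,
                     col = cols[pmin(seg$order, 3)], lwd = 2)
  if (nrow(network$branch_points))
    graphics::points(network$branch_points$x, network$branch_points$y,
                     pch = 16, cex = 0.5)
  invisible(network)
}

#' Plot a scalar field on scattered points
#' @param coords m x 2 positions.
#' @param values Per-point values.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_field <- function(coords, values, ...) {
  pal <- grDevices::hcl.colors(64, "viridis")
  idx <- cut(values, 64, labels = FALSE)
  graphics::plot(coords[, 1], coords[, 2], col = pal[idx], pch = 15,
                 cex = 0.6, asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(NULL)
}
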