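# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_tile labs scale_x_log10 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot an isotherm fit: data points and fitted binding curve
#' @param object An [fit_isotherm()] result.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @export
autoplot.isotherm_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  p <- ggplot(dat, aes(x = conc, y = delta_fnorm)) +
    geom_point(alpha = 0.7) +
    scale_x_log10() +
    labs(x = "ligand concentration (nM)",
         y = expression(Delta * F[norm]),
         title = if (object$no_binding_flag) "no binding detected" else
           sprintf("Kd = %.3g +/- %.2g nM", object$kd, object$kd_se)) +
    theme_minimal()
  if (!object$no_binding_flag && isTRUE(object$converged)) {
    cr <- range(dat$conc[dat$conc > 0])
    cc <- 10^seq(log10(cr[1]), log10(cr[2]), length.out = n_curve)
    p_eff <- if (object$model == "hyperbolic") 0 else object$protein_conc
    curve <- tibble(
      conc = cc,
      delta_fnorm = object$offset +
        object$amplitude * fraction_bound(cc, object$kd, p_eff))
    p <- p + geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Plot a per-residue stability-change profile
#' @param object A [delta_g_profile()] result.
#' @param ... Unused.
#' @export
autoplot.stability_profile <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot(object, aes(x = res_seq, y = delta_g, fill = flagged)) +
    geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    facet_wrap(~chain, ncol = 1) +
    labs(x = "residue", y = expression(Delta * G[i] ~ "(kcal/mol)")) +
    theme_minimal()
}

#' Plot an occupancy grid as a z-projected heat map
#' @param object An [occupancy_grid()].
#' @param ... Unused.
#' @export
autoplot.occupancy_grid <- function(object, ...) {
  tb <- as_tibble(object)
  proj <- dplyr::summarise(dplyr::group_by(tb, x, y),
                           count = sum(count), .groups = "drop")
  ggplot(proj, aes(x = x, y = y, fill = count)) +
    geom_tile(width = object$bin_edge, height = object$bin_edge) +
    ggplot2::coord_equal() +
    labs(x = "x (A)", y = "y (A)", fill = "frames") +
    theme_minimal()
}

#' Bar plot of per-residue contact propensities
#' @param propensity A [hbond_saltbridge_propensity()] tibble.
#' @export
plot_propensity <- function(propensity) {
  p <- ggplot(propensity, aes(x = res_seq, y = propensity)) +
    geom_col() +
    labs(x = "residue", y = "contact propensity (fraction of frames)") +
    theme_minimal()
  if ("chain" %in% names(propensity)) p <- p + facet_wrap(~chain, ncol = 1)
  p
}

#' Bound/apo RMSF comparison plot
#' @param comparison A [rmsf_compare()] tibble.
#' @export
plot_rmsf_compare <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, c("rmsf_bound", "rmsf_apo"),
                              names_to = "condition", names_prefix = "rmsf_",
                              values_to = "rmsf")
  ggplot(long, aes(x = res_seq, y = rmsf, colour = condition)) +
    geom_line() +
    facet_wrap(~chain, ncol = 1) +
    labs(x = "residue", y = "C-alpha RMSF (A)") +
    theme_minimal()
}

#' Dendrogram of a pose linkage tree (delta heights)
#' @param tree A [ward_linkage()] result.
#' @param threshold Optional cut threshold drawn as a dashed line.
#' @export
plot_dendrogram <- function(tree, threshold = NULL) {
  hc <- tree$hclust
  hc$height <- hc$height / sqrt(2)
  dend <- stats::as.dendrogram(hc)
  # base-graphics dendrograms are the lingua franca here; wrap in ggplot
  # via segment extraction
  seg <- dendrogram_segments(dend)
  p <- ggplot(seg, aes(x = x, y = y, xend = xend, yend = yend)) +
    ggplot2::geom_segment() +
    labs(x = "pose", y = expression(delta ~ "(A)")) +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

# flatten a dendrogram into line segments
dendrogram_segments <- function(dend) {
  segs <- list()
  xpos <- new.env(parent = emptyenv()); xpos$next_x <- 0
  walk <- function(node) {
    if (stats::is.leaf(node)) {
      xpos$next_x <- xpos$next_x + 1
      return(c(x = xpos$next_x, y = 0))
    }
    left <- walk(node[[1]]); right <- walk(node[[2]])
    h <- attr(node, "height")
    segs[[length(segs) + 1]] <<- tibble(
      x = c(left["x"], left["x"], right["x"]),
      y = c(left["y"], h, h),
      xend = c(left["x"], right["x"], right["x"]),
      yend = c(h, h, right["y"]))
    c(x = mean(c(left["x"], right["x"])), y = h)
  }
  walk(dend)
  dplyr::bind_rows(segs)
}
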