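# Ensemble statistics on two chosen species: binned occupancy frequencies,
# the quasi-potential surface U = -ln(P), and deterministic attractor
# counting for bistability analysis.

#' Estimate a quasi-potential landscape from ensemble states
#'
#' Bins the sampled states of two species into a 2-D histogram, normalises
#' to occupancy frequencies P, and forms the quasi-potential approximation
#' `U = -ln(P + epsilon)`. The pseudo-frequency `epsilon` (default
#' `1 / (2 * n_samples)`, half the weight of one sample) keeps U finite on
#' empty bins; its bias vanishes as the sample count grows. Minima of U are
#' the metastable states of the system.
#'
#' @param samples matrix of states (rows = samples), with species names as
#'   column names; typically [pool_snapshots()] output.
#' @param axis_species character pair naming the two species to bin.
#' @param n_bins bins per axis (>= 2).
#' @param epsilon pseudo-frequency added to P before the logarithm.
#' @param ranges optional list of two length-2 numeric ranges; defaults to
#'   the sample range per axis. A degenerate (zero-range) axis collapses to
#'   a single bin with a warning.
#' @return an object of class `landscape_grid`: bin edges and centers per
#'   axis, the frequency matrix `P` (sums to 1) and potential matrix `U`.
#' @examples
#' xy <- cbind(A = rnorm(2000, 50, 8), B = rnorm(2000, 30, 5))
#' g <- estimate_landscape(xy, c("A", "B"), n_bins = 20)
#' range(g$U)
#' @export
estimate_landscape <- function(samples, axis_species = colnames(samples)[1:2],
                               n_bins = 40L, epsilon = NULL, ranges = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("landscape estimation needs at least one sample")
  if (length(axis_species) != 2L)
    stop("`axis_species` must name exactly two species")
  if (!all(axis_species %in% colnames(samples)))
    stop("axis species not found among sample columns")
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  n <- nrow(samples)
  if (is.null(epsilon)) epsilon <- 1 / (2 * n)
  if (epsilon <= 0) stop("`epsilon` must be positive")
  axis <- function(k) {
    v <- samples[, axis_species[k]]
    r <- if (is.null(ranges)) range(v) else ranges[[k]]
    if (diff(r) <= 0) {
      warning(sprintf("axis %s has zero range; using a single bin", axis_species[k]))
      return(list(edges = c(r[1] - 0.5, r[1] + 0.5), idx = rep(1L, n)))
    }
    edges <- seq(r[1], r[2], length.out = n_bins + 1L)
    idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    list(edges = edges, idx = idx)
  }
  ax <- axis(1L); ay <- axis(2L)
  nbx <- length(ax$edges) - 1L; nby <- length(ay$edges) - 1L
  P <- matrix(tabulate(ax$idx + nbx * (ay$idx - 1L), nbins = nbx * nby) / n,
              nbx, nby)
  U <- -log(P + epsilon)
  structure(list(axis_species = axis_species,
                 edges_x = ax$edges, edges_y = ay$edges,
                 mids_x = (ax$edges[-1] + ax$edges[-(nbx + 1L)]) / 2,
                 mids_y = (ay$edges[-1] + ay$edges[-(nby + 1L)]) / 2,
                 P = P, U = U, epsilon = epsilon, n_samples = n),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("Quasi-potential landscape over (%s, %s): %d x %d bins, %d samples\n",
              x$axis_species[1], x$axis_species[2],
              nrow(x$P), ncol(x$P), x$n_samples))
  mins <- landscape_minima(x)
  cat(sprintf("  %d local minim%s of U (interior, 8-neighborhood)\n",
              nrow(mins), if (nrow(mins) == 1) "um" else "a"))
  invisible(x)
}

#' @export
plot.landscape_grid <- function(x, ...) {
  graphics::image(x$mids_x, x$mids_y, x$U,
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE),
                  xlab = x$axis_species[1], ylab = x$axis_species[2],
                  main = "quasi-potential U = -ln P", ...)
  m <- landscape_minima(x)
  if (nrow(m)) graphics::points(m$x, m$y, pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}

#' Local minima of a quasi-potential surface
#'
#' A bin is a local minimum when its potential is strictly below all its
#' 8-neighbors. Boundary bins are excluded: sparse histograms produce edge
#' artifacts there, and the attractors of a well-sampled system sit in the
#' interior of the sampled range.
#'
#' @param grid a [estimate_landscape()] result.
#' @return data.frame with bin indices (`ix`, `iy`), bin-center coordinates
#'   (`x`, `y`) and the local `U` and `P` values, one row per minimum,
#'   ordered by increasing U (deepest first).
#' @export
landscape_minima <- function(grid) {
  U <- grid$U
  nx <- nrow(U); ny <- ncol(U)
  out <- NULL
  if (nx >= 3L && ny >= 3L) {
    for (i in 2:(nx - 1L)) for (j in 2:(ny - 1L)) {
      u <- U[i, j]
      nb <- U[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
      if (sum(nb > u) == 8L)  # strictly below all 8 neighbors
        out <- rbind(out, data.frame(ix = i, iy = j,
                                     x = grid$mids_x[i], y = grid$mids_y[j],
                                     U = u, P = grid$P[i, j]))
    }
  }
  if (is.null(out))
    out <- data.frame(ix = integer(0), iy = integer(0), x = numeric(0),
                      y = numeric(0), U = numeric(0), P = numeric(0))
  out[order(out$U), , drop = FALSE]
}

#' Export a landscape grid as TSV
#'
#' Long-format table with one row per bin: bin-center coordinates of both
#' axis species, occupancy frequency P and quasi-potential U.
#'
#' @param grid a [estimate_landscape()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_landscape <- function(grid, path) {
  df <- expand.grid(x = grid$mids_x, y = grid$mids_y)
  names(df) <- grid$axis_species
  df$P <- as.vector(grid$P)
  df$U <- as.vector(grid$U)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count deterministic attractors by multistart integration
#'
#' Integrates an ODE system from `n_starts` uniform random initial states in
#' `init_box` to `t_long` and clusters the endpoints: endpoints within
#' `merge_radius` (Euclidean) of an already-found attractor join it,
#' otherwise they found a new one. Starts whose trajectory is still moving
#' at `t_long` (relative change above `conv_tol` over the last 10% of the
#' horizon) are excluded with a warning; if every start is excluded, an
#' error is raised.
#'
#' @param ode_rhs deSolve-style `function(t, y, parms)`, e.g. [ast_ode_rhs()].
#' @param n_starts number of random initial states (>= 10).
#' @param init_box list or matrix giving per-species `lower` and `upper`
#'   bounds of the initial-state box.
#' @param t_long integration horizon (model time units).
#' @param merge_radius attractor merge distance (same units as the states).
#' @param seed integer seed for the random starts.
#' @param rtol relative integration tolerance.
#' @param conv_tol relative end-of-run movement above which a start is
#'   deemed non-convergent.
#' @return an object of class `attractor_report`: matrix `attractors` (one
#'   row per attractor, ordered by decreasing basin count), integer
#'   `basin_counts`, `n_used`, and the tolerances used.
#' @examples
#' \donttest{
#' rep <- count_attractors(ast_ode_rhs(0.2), n_starts = 40,
#'                         init_box = list(lower = rep(0, 4),
#'                                         upper = rep(3 * 6023, 4)),
#'                         merge_radius = 0.05 * 6023, seed = 1)
#' rep$attractors
#' }
#' @export
count_attractors <- function(ode_rhs, n_starts = 100L, init_box,
                             t_long = 200, merge_radius, seed = NULL,
                             rtol = 1e-8, conv_tol = 1e-4) {
  if (n_starts < 10L) stop("`n_starts` must be at least 10")
  if (is.matrix(init_box)) init_box <- list(lower = init_box[1, ], upper = init_box[2, ])
  lo <- init_box$lower; hi <- init_box$upper
  if (length(lo) != length(hi) || any(hi < lo)) stop("malformed `init_box`")
  ns <- length(lo)
  if (missing(merge_radius) || merge_radius <= 0)
    stop("`merge_radius` must be a positive distance")
  if (!is.null(seed)) set.seed(as.integer(seed))
  starts <- matrix(runif(n_starts * ns, rep(lo, each = n_starts),
                         rep(hi, each = n_starts)), n_starts, ns)
  tchk <- 0.9 * t_long
  ends <- matrix(NA_real_, n_starts, ns)
  ok <- logical(n_starts)
  for (i in seq_len(n_starts)) {
    sol <- tryCatch(
      deSolve::ode(y = starts[i, ], times = c(0, tchk, t_long), func = ode_rhs,
                   parms = NULL, rtol = rtol, atol = rtol * max(hi, 1)),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 3L || anyNA(sol)) next
    y_chk <- sol[2, -1]; y_end <- sol[3, -1]
    move <- max(abs(y_end - y_chk) / (1 + abs(y_end)))
    if (move > conv_tol) next
    ends[i, ] <- y_end
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no start converged; increase `t_long` or loosen `conv_tol`")
  if (any(!ok))
    warning(sprintf("%d of %d starts excluded as non-convergent", sum(!ok), n_starts))
  ends <- ends[ok, , drop = FALSE]
  centers <- NULL
  members <- list()
  for (i in seq_len(nrow(ends))) {
    assigned <- FALSE
    if (!is.null(centers)) {
      d <- sqrt(rowSums((centers - matrix(ends[i, ], nrow(centers), ns,
                                          byrow = TRUE))^2))
      k <- which.min(d)
      if (d[k] < merge_radius) {
        members[[k]] <- c(members[[k]], i)
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centers <- rbind(centers, ends[i, ])
      members[[length(members) + 1L]] <- i
    }
  }
  att <- do.call(rbind, lapply(members, function(m)
    colMeans(ends[m, , drop = FALSE])))
  counts <- vapply(members, length, integer(1))
  ord <- order(-counts, -att[, 1])
  structure(list(attractors = att[ord, , drop = FALSE],
                 basin_counts = counts[ord],
                 n_used = nrow(ends), n_starts = n_starts,
                 merge_radius = merge_radius, t_long = t_long),
            class = "attractor_report")
}

#' @export
print.attractor_report <- function(x, ...) {
  cat(sprintf("Attractor report: %d attractor%s from %d converged starts (merge radius %g)\n",
              nrow(x$attractors), if (nrow(x$attractors) == 1) "" else "s",
              x$n_used, x$merge_radius))
  for (k in seq_len(nrow(x$attractors)))
    cat(sprintf("  #%d (basin %d): %s\n", k, x$basin_counts[k],
                paste(sprintf("%.4g", x$attractors[k, ]), collapse = ", ")))
  invisible(x)
}

#' Export an attractor report as JSON
#'
#' @param report a [count_attractors()] result.
#' @param path output file path.
#' @param species optional species names for the attractor coordinates.
#' @return the path, invisibly.
#' @export
write_attractors <- function(report, path, species = NULL) {
  att <- report$attractors
  if (!is.null(species)) colnames(att) <- species
  obj <- list(n_attractors = nrow(att),
              attractors = lapply(seq_len(nrow(att)), function(k)
                as.list(stats::setNames(att[k, ], colnames(att)))),
              basin_counts = report$basin_counts,
              n_converged = report$n_used,
              merge_radius = report$merge_radius,
              t_long = report$t_long)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
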