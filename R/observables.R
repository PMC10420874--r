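#' Unwrap a bonded molecule across periodic boundaries
#'
#' Rebuilds internally consistent coordinates for one molecule by walking its
#' bond graph from the first listed bead and accumulating minimum-image
#' displacements. Required before any gyration analysis, since the engine
#' stores wrapped coordinates.
#'
#' @param state a [dpd_system()].
#' @param indices bead indices of the molecule (default: the polymer chain
#'   recorded by the builder in `state$meta$polymer`).
#' @return A `length(indices) x 3` matrix of unwrapped coordinates (rows in
#'   the order of `indices`).
#' @export
unwrap_chain <- function(state, indices = state$meta$polymer) {
  if (is.null(indices) || !length(indices))
    stop("no bead indices to unwrap")
  pos <- state$positions[indices, , drop = FALSE]
  n <- length(indices)
  if (n == 1) return(pos)
  L <- state$box$lengths
  b <- state$topology$bonds
  keep <- b$i %in% indices & b$j %in% indices
  bi <- match(b$i[keep], indices)
  bj <- match(b$j[keep], indices)
  if (!length(bi)) return(pos) # unbonded set: positions used as stored
  adj <- vector("list", n)
  for (e in seq_along(bi)) {
    adj[[bi[e]]] <- c(adj[[bi[e]]], bj[e])
    adj[[bj[e]]] <- c(adj[[bj[e]]], bi[e])
  }
  out <- pos
  visited <- logical(n)
  visited[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (visited[nb]) next
      d <- pos[nb, ] - out[cur, ]
      d <- d - L * round(d / L)
      out[nb, ] <- out[cur, ] + d
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  if (!all(visited))
    warning("molecule bond graph is disconnected; ",
            sum(!visited), " bead(s) left wrapped")
  out
}

#' Radius of gyration
#'
#' Rg = sqrt( (1/N) sum_i |r_i - r_com|^2 ). Coordinates must already be
#' unwrapped along the molecule (see [unwrap_chain()]).
#'
#' @param positions n x 3 coordinate matrix.
#' @return Scalar Rg in rc units.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))) # 0.5
#' @export
radius_of_gyration <- function(positions) {
  positions <- as.matrix(positions)
  if (!nrow(positions)) stop("need at least one bead")
  com <- colMeans(positions)
  sqrt(mean(rowSums(sweep(positions, 2, com)^2)))
}

#' Gyration tensor, eigenvalues and shape factor
#'
#' The gyration tensor is the second-moment tensor of bead positions about
#' the centre of mass, S_ab = (1/N) sum_i (r_ia - r_com,a)(r_ib - r_com,b).
#' Its trace equals Rg^2 and its sorted eigenvalues L1^2 >= L2^2 >= L3^2
#' summarise the molecular shape via the shape factor
#' delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L3^2 L1^2) / (L1^2+L2^2+L3^2)^2:
#' 0 for an isotropic (sphere-like) distribution, 1 for a perfect rod.
#'
#' @param positions n x 3 coordinate matrix (unwrapped).
#' @return An object of class `gyration_result`: `rg2`, `tensor` (3 x 3),
#'   `eigenvalues` (descending, >= 0), `delta`.
#' @export
gyration_tensor <- function(positions) {
  positions <- as.matrix(positions)
  if (!nrow(positions)) stop("need at least one bead")
  com <- colMeans(positions)
  d <- sweep(positions, 2, com)
  S <- crossprod(d) / nrow(positions)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 0) # clip tiny negative round-off
  res <- structure(list(rg2 = sum(diag(S)), tensor = S, eigenvalues = ev,
                        delta = NA_real_),
                   class = "gyration_result")
  res$delta <- shape_factor(res)
  res
}

#' @rdname gyration_tensor
#' @param x a `gyration_result` or a numeric vector of the three gyration
#'   eigenvalues.
#' @return `shape_factor()`: scalar delta in \[0, 1\]; a degenerate all-zero
#'   eigenvalue set (all beads coincident) gives 0.
#' @export
shape_factor <- function(x) {
  ev <- if (inherits(x, "gyration_result")) x$eigenvalues else as.numeric(x)
  if (length(ev) != 3 || any(ev < 0)) stop("need three non-negative eigenvalues")
  s <- sum(ev)
  if (s <= 0) return(0)
  d <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / s^2
  min(max(d, 0), 1)
}

#' @export
print.gyration_result <- function(x, ...) {
  cat(sprintf("<gyration: Rg = %.4g rc, delta = %.4g, L^2 = (%.4g, %.4g, %.4g)>\n",
              sqrt(x$rg2), x$delta, x$eigenvalues[1], x$eigenvalues[2],
              x$eigenvalues[3]))
  invisible(x)
}

#' Orientational order parameter
#'
#' P = < (3 cos^2 theta - 1) / 2 > with theta the angle of each vector
#' against the +z membrane normal: 1 for alignment with the normal, -0.5 for
#' in-plane vectors, 0 for an isotropic distribution.
#'
#' @param vectors numeric length-3 vector or n x 3 matrix of nonzero vectors.
#' @return Scalar P in \[-0.5, 1\].
#' @examples
#' order_parameter(c(0, 0, 1))  # 1
#' order_parameter(c(1, 0, 0))  # -0.5
#' @export
order_parameter <- function(vectors) {
  v <- if (is.null(dim(vectors))) matrix(vectors, 1) else as.matrix(vectors)
  if (ncol(v) != 3) stop("vectors must have three components")
  n2 <- rowSums(v^2)
  if (any(n2 <= 0)) stop("order parameter is undefined for zero vectors")
  cos2 <- v[, 3]^2 / n2
  mean((3 * cos2 - 1) / 2)
}

#' Order-parameter profile of the lipid head chains
#'
#' Bins the per-lipid head-chain order parameter along one axis inside a
#' lateral region (default the interaction zone x, y in \[20, 60) rc). Each
#' lipid contributes the mean P over its head-chain vectors; the default
#' vector rule uses the bonds between consecutive head beads, the
#' alternative the head chain's end-to-end vector. Lipids are assigned to
#' bins by the midpoint of their head beads; bins containing no lipid are
#' reported as NA, not 0.
#'
#' @param state a [dpd_system()] with builder metadata (`meta$head_idx`).
#' @param region list with `x` and `y` half-open intervals in rc.
#' @param bin_width bin width along `axis` in rc (default 2).
#' @param axis `"x"` or `"y"`.
#' @param vector_rule `"bond"` (consecutive head-bead bonds) or
#'   `"end_to_end"`.
#' @return An object of class `order_profile`: data.frame with `lo`, `hi`,
#'   `mid`, `P`, `n_lipids`, plus attributes recording the rule and region.
#' @export
order_parameter_profile <- function(state,
                                    region = list(x = c(20, 60),
                                                  y = c(20, 60)),
                                    bin_width = 2, axis = c("x", "y"),
                                    vector_rule = c("bond", "end_to_end")) {
  axis <- match.arg(axis)
  vector_rule <- match.arg(vector_rule)
  H <- state$meta$head_idx
  if (is.null(H)) stop("state carries no per-lipid head-bead metadata")
  L <- state$box$lengths
  ax <- if (axis == "x") 1L else 2L
  nlip <- nrow(H)
  Pl <- numeric(nlip); midx <- numeric(nlip); midy <- numeric(nlip)
  for (l in seq_len(nlip)) {
    idx <- H[l, ]
    p <- state$positions[idx, , drop = FALSE]
    # unwrap the head chain relative to its first bead
    for (m in seq_len(nrow(p))[-1]) {
      d <- p[m, ] - p[m - 1, ]
      p[m, ] <- p[m - 1, ] + (d - L * round(d / L))
    }
    vecs <- if (vector_rule == "bond") diff(p) else
      matrix(p[nrow(p), ] - p[1, ], 1)
    Pl[l] <- order_parameter(vecs)
    mid <- colMeans(p)
    midx[l] <- mid[1] %% L[1]; midy[l] <- mid[2] %% L[2]
  }
  inreg <- midx >= region$x[1] & midx < region$x[2] &
           midy >= region$y[1] & midy < region$y[2]
  lim <- if (axis == "x") region$x else region$y
  edges <- seq(lim[1], lim[2], by = bin_width)
  if (edges[length(edges)] < lim[2]) edges <- c(edges, lim[2])
  mids <- if (axis == "x") midx else midy
  bin <- findInterval(mids, edges, rightmost.closed = FALSE)
  out <- data.frame(lo = edges[-length(edges)], hi = edges[-1])
  out$mid <- (out$lo + out$hi) / 2
  out$P <- NA_real_
  out$n_lipids <- 0L
  for (bn in seq_len(nrow(out))) {
    sel <- inreg & bin == bn
    out$n_lipids[bn] <- sum(sel)
    if (any(sel)) out$P[bn] <- mean(Pl[sel])
  }
  structure(out, class = c("order_profile", "data.frame"),
            axis = axis, vector_rule = vector_rule, region = region)
}

#' Head beads in a detachment slab
#'
#' Counts lipid head (type H) beads whose z coordinate lies in the half-open
#' slab \[z_lo, z_hi). The default slab \[10, 15) rc sits above the
#' equilibrium bilayer (z in about 1-9 rc), so a nonzero count signals lipids
#' detached from the membrane.
#'
#' @param state a [dpd_system()].
#' @param z_lo,z_hi slab bounds in rc, `z_lo < z_hi`.
#' @return Integer count nH.
#' @export
slab_head_count <- function(state, z_lo = 10, z_hi = 15) {
  if (!(z_lo < z_hi)) stop("z_lo must be < z_hi")
  z <- state$positions[state$types == "H", 3]
  sum(z >= z_lo & z < z_hi)
}

#' Detached fraction of the upper leaflet
#'
#' 100 * nH / n0H: the slab head-bead count as a percentage of the total
#' upper-leaflet head beads.
#'
#' @param nH slab head-bead count.
#' @param n0H total upper-leaflet head beads, > 0.
#' @return Percentage (not rounded; round to one decimal for reporting).
#' @examples
#' fraction_of_upper_leaflet(480, 79753) # about 0.6 percent
#' @export
fraction_of_upper_leaflet <- function(nH, n0H) {
  if (n0H <= 0) stop("n0H must be positive")
  100 * nH / n0H
}

#' Rod-coil transition period from a shape-factor series
#'
#' The transition period trc is the elapsed time from the first up-crossing
#' of the rod threshold by delta(t) to the subsequent down-crossing of the
#' coil threshold. If the series never reaches the rod threshold, or never
#' returns below the coil threshold afterwards, the result is flagged as not
#' detected (no error is raised).
#'
#' @param time observation times (tau), uniform stride.
#' @param delta shape-factor series, same length.
#' @param rod_threshold rod threshold (default 0.8).
#' @param coil_threshold coil threshold (default 0.3), < rod_threshold.
#' @return An object of class `transition_period`: `trc`, `t_rod`, `t_coil`,
#'   `detected`, thresholds.
#' @export
detect_transition_period <- function(time, delta, rod_threshold = 0.8,
                                     coil_threshold = 0.3) {
  if (!(rod_threshold > coil_threshold))
    stop("rod_threshold must exceed coil_threshold")
  if (length(time) != length(delta)) stop("time and delta lengths differ")
  res <- structure(list(trc = NA_real_, t_rod = NA_real_, t_coil = NA_real_,
                        detected = FALSE, rod_threshold = rod_threshold,
                        coil_threshold = coil_threshold),
                   class = "transition_period")
  i_rod <- which(delta >= rod_threshold)[1]
  if (is.na(i_rod)) return(res)
  later <- which(delta <= coil_threshold & seq_along(delta) > i_rod)[1]
  if (is.na(later)) return(res)
  res$t_rod <- time[i_rod]
  res$t_coil <- time[later]
  res$trc <- time[later] - time[i_rod]
  res$detected <- TRUE
  res
}

#' @export
print.transition_period <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<rod-coil transition: trc = %.3g tau (rod at %.3g, coil at %.3g)>\n",
                x$trc, x$t_rod, x$t_coil))
  else cat("<rod-coil transition: not detected>\n")
  invisible(x)
}

#' Aggregate transition periods over replicas
#'
#' Averages the detected per-replica periods and reports the mean error
#' (standard error of the mean); replicas without a detected transition are
#' dropped but counted.
#'
#' @param periods list of [detect_transition_period()] results (or numeric
#'   periods).
#' @return List: `trc_mean`, `trc_se`, `values`, `n_detected`, `n_total`.
#' @export
aggregate_transition_periods <- function(periods) {
  vals <- vapply(periods, function(p)
    if (inherits(p, "transition_period")) p$trc else as.numeric(p),
    numeric(1))
  det <- vals[!is.na(vals)]
  list(trc_mean = if (length(det)) mean(det) else NA_real_,
       trc_se = if (length(det) > 1) sd(det) / sqrt(length(det)) else NA_real_,
       values = vals, n_detected = length(det), n_total = length(vals))
}
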