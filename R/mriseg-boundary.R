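#' Exact minimal-cost circular path through a polar cost image
#'
#' Finds the circular surface r(theta) minimising the summed per-column cost
#' subject to the smoothness constraint |r(j+1) - r(j)| <= delta for adjacent
#' angle columns, including wrap-around between the last and first column.
#' Solved exactly: a dynamic program is run over all start radii
#' simultaneously (matrix-valued states), then the winning start is traced
#' back. For a single surface this is equivalent to the minimum-cut
#' formulation used for optimal surface detection.
#'
#' @param cost numeric matrix, angles in rows, radii in columns; `Inf` (or
#'   very large) entries are forbidden.
#' @param delta maximum radius change (in samples) between adjacent columns.
#' @return list with `radius_idx` (one 1-based radius index per angle) and
#'   `cost` (total path cost).
#' @export
min_circular_path <- function(cost, delta = 2L) {
  stopifnot(is.matrix(cost), delta >= 0)
  n_a <- nrow(cost); n_r <- ncol(cost)
  BIG <- 1e12
  cost[!is.finite(cost)] <- BIG
  if (n_a == 1L) {
    r <- which.min(cost[1, ])
    return(list(radius_idx = r, cost = cost[1, r]))
  }

  # phase 1: DP over all start radii at once. D[s, r] = best cost of a path
  # starting at radius s in column 1 and sitting at radius r in column j.
  D <- matrix(BIG, n_r, n_r)
  diag(D) <- cost[1, ]
  for (j in 2:n_a) {
    M <- D
    for (s in seq_len(delta)) {
      if (s >= n_r) break
      M[, 1:(n_r - s)] <- pmin(M[, 1:(n_r - s)], D[, (1 + s):n_r])
      M[, (1 + s):n_r] <- pmin(M[, (1 + s):n_r], D[, 1:(n_r - s)])
    }
    D <- sweep(M, 2, cost[j, ], `+`)
    D[D > BIG] <- BIG
  }
  # circular closure: end radius within delta of the start radius
  close_ok <- abs(outer(seq_len(n_r), seq_len(n_r), `-`)) <= delta
  Dc <- D; Dc[!close_ok] <- BIG
  best <- which(Dc == min(Dc), arr.ind = TRUE)[1, ]
  total <- Dc[best[1], best[2]]
  if (total >= BIG) stop("no circular path satisfies |delta r| <= ", delta)

  # phase 2: scalar DP with traceback for the winning start radius
  s0 <- best[1]
  V <- matrix(BIG, n_a, n_r)
  parent <- matrix(NA_integer_, n_a, n_r)
  V[1, s0] <- cost[1, s0]
  for (j in 2:n_a) {
    for (r in seq_len(n_r)) {
      lo <- max(1L, r - delta); hi <- min(n_r, r + delta)
      prev <- V[j - 1, lo:hi]
      k <- which.min(prev)
      V[j, r] <- prev[k] + cost[j, r]
      parent[j, r] <- lo + k - 1L
    }
  }
  ends <- which(abs(seq_len(n_r) - s0) <= delta)
  r_end <- ends[which.min(V[n_a, ends])]
  path <- integer(n_a)
  path[n_a] <- r_end
  for (j in (n_a - 1):1) path[j] <- parent[j + 1, path[j + 1]]
  list(radius_idx = path, cost = V[n_a, r_end])
}

#' Brute-force minimal circular path (oracle)
#'
#' Enumerates every feasible circular path on a small polar grid and returns
#' the cheapest; exponential, for verifying [min_circular_path()] only.
#' @inheritParams min_circular_path
#' @return same structure as [min_circular_path()].
#' @export
brute_force_circular_path <- function(cost, delta = 2L) {
  n_a <- nrow(cost); n_r <- ncol(cost)
  stopifnot(n_a <= 10, n_r <= 8)
  paths <- matrix(seq_len(n_r), ncol = 1)
  for (j in 2:n_a) {
    grown <- vector("list", nrow(paths))
    for (i in seq_len(nrow(paths))) {
      last <- paths[i, j - 1]
      nxt <- seq(max(1L, last - delta), min(n_r, last + delta))
      grown[[i]] <- cbind(matrix(rep(paths[i, ], length(nxt)),
                                 nrow = length(nxt), byrow = TRUE), nxt)
    }
    paths <- do.call(rbind, grown)
  }
  feasible <- abs(paths[, n_a] - paths[, 1]) <= delta
  paths <- paths[feasible, , drop = FALSE]
  costs <- rowSums(matrix(cost[cbind(rep(seq_len(n_a), each = nrow(paths)),
                                     as.vector(paths))],
                          nrow(paths), n_a))
  k <- which.min(costs)
  list(radius_idx = paths[k, ], cost = costs[k])
}

#' Detect the outer (skin) and inner (SAT/internal) boundaries
#'
#' The outer boundary is taken from the body mask: for each angle, the last
#' radius still inside the mask, regularised by a delta-constrained minimal
#' path so the curve is smooth and circularly closed. The inner boundary is
#' the minimal circular path through `-dI/dr` (the strongest muscle-to-fat
#' radial edge), restricted to radii strictly inside the outer curve.
#'
#' After the discrete path is found, each boundary is refined to sub-sample
#' precision: the outer curve by the 0.5-crossing of the interpolated body
#' mask along the ray, the inner curve by the crossing of the mid-level
#' between the tissues on either side of the edge. The integer path indices
#' are kept alongside the refined radii.
#'
#' @param polar a `polar_image` of the (bias-corrected) slice.
#' @param polar_mask a `polar_image` of the body mask, same geometry.
#' @param delta smoothness constraint in radial samples per angle step.
#' @param refine apply sub-sample refinement (default `TRUE`).
#' @return list of two `boundary_curve`s: `outer`, `inner`.
#' @export
detect_sat_boundaries <- function(polar, polar_mask, delta = 2L,
                                  refine = TRUE) {
  stopifnot(inherits(polar, "polar_image"), inherits(polar_mask, "polar_image"))
  n_a <- nrow(polar$samples); n_r <- ncol(polar$samples)

  inside <- polar_mask$samples >= 0.5
  r_mask <- apply(inside, 1, function(row) {
    w <- which(row)
    if (!length(w)) NA_integer_ else max(w)
  })
  if (anyNA(r_mask)) stop("body mask does not cover the centre at every angle")
  cost_outer <- abs(outer(rep(1, n_a), seq_len(n_r)) - r_mask)
  outer_fit <- min_circular_path(cost_outer, delta)

  grad <- t(apply(polar$samples, 1, function(row) {
    c(diff(row), 0) + c(0, diff(row))
  })) / 2                                    # centred dI/dr
  cost_inner <- -grad
  # forbid radii at or beyond the outer curve (leave a 2-sample guard)
  for (a in seq_len(n_a)) {
    hi <- max(2L, outer_fit$radius_idx[a] - 2L)
    if (hi < n_r) cost_inner[a, hi:n_r] <- Inf
    cost_inner[a, 1L] <- Inf                 # centre itself is not a boundary
  }
  inner_fit <- min_circular_path(cost_inner, delta)

  out_c <- boundary_curve(outer_fit$radius_idx, polar$radial_step_mm, delta)
  in_c <- boundary_curve(inner_fit$radius_idx, polar$radial_step_mm, delta)
  if (refine) {
    out_c$radius_mm <- refine_crossing(polar_mask$samples, outer_fit$radius_idx,
                                       polar$radial_step_mm, level = 0.5)
    in_c$radius_mm <- refine_midlevel(polar$samples, inner_fit$radius_idx,
                                      polar$radial_step_mm)
  }
  list(outer = out_c, inner = in_c)
}

# sub-sample edge localisation: crossing of a fixed level along each ray
refine_crossing <- function(samples, radius_idx, step_mm, level) {
  n_r <- ncol(samples)
  vapply(seq_len(nrow(samples)), function(a) {
    r <- radius_idx[a]
    row <- samples[a, ]
    for (j in max(2L, r - 2L):min(n_r - 1L, r + 2L)) {
      if ((row[j] - level) * (row[j + 1] - level) <= 0 && row[j] != row[j + 1])
        return((j - 1 + (level - row[j]) / (row[j + 1] - row[j])) * step_mm)
    }
    (r - 1) * step_mm
  }, numeric(1))
}

# crossing of the midpoint between the intensities just inside and outside
refine_midlevel <- function(samples, radius_idx, step_mm) {
  n_r <- ncol(samples)
  vapply(seq_len(nrow(samples)), function(a) {
    r <- radius_idx[a]
    row <- samples[a, ]
    level <- (row[max(1L, r - 3L)] + row[min(n_r, r + 3L)]) / 2
    for (j in max(2L, r - 3L):min(n_r - 1L, r + 2L)) {
      if ((row[j] - level) * (row[j + 1] - level) <= 0 && row[j] != row[j + 1])
        return((j - 1 + (level - row[j]) / (row[j + 1] - row[j])) * step_mm)
    }
    (r - 1) * step_mm
  }, numeric(1))
}

#' Boundary curve (one radius per angle)
#' @param radius_idx 1-based radial sample index per angle column.
#' @param radial_step_mm radial sampling step.
#' @param smoothness_delta the delta the curve satisfies.
#' @return a `boundary_curve`.
#' @export
boundary_curve <- function(radius_idx, radial_step_mm, smoothness_delta) {
  n <- length(radius_idx)
  if (abs(radius_idx[1] - radius_idx[n]) > smoothness_delta)
    stop("curve violates circular closure")
  structure(list(radius_idx = as.integer(radius_idx),
                 radial_step_mm = radial_step_mm,
                 smoothness_delta = smoothness_delta),
            class = "boundary_curve")
}

#' Radii of a boundary curve in millimetres
#'
#' Returns the sub-sample refined radii when present, otherwise the discrete
#' path radii.
#' @param curve a `boundary_curve`.
#' @export
boundary_radius_mm <- function(curve) {
  if (!is.null(curve$radius_mm)) curve$radius_mm
  else (curve$radius_idx - 1) * curve$radial_step_mm
}

#' Rasterise the annulus between two boundary curves back to the slice grid
#'
#' Classifies every cartesian pixel by its polar coordinates relative to the
#' centre used for unrolling: pixels whose radius falls strictly between the
#' (angle-interpolated) inner and outer curves form the SAT mask.
#'
#' @param outer,inner `boundary_curve`s from [detect_sat_boundaries()].
#' @param polar the `polar_image` they were detected on.
#' @return logical matrix of the source slice's dimensions.
#' @export
sat_mask_from_boundaries <- function(outer, inner, polar) {
  stopifnot(inherits(polar, "polar_image"))
  if (any(inner$radius_idx >= outer$radius_idx))
    stop("inner boundary must lie strictly inside the outer boundary")
  d <- polar$src_dim
  xg <- (matrix(seq_len(d[1]), d[1], d[2]) - polar$center_px[1]) * polar$spacing_mm[1]
  yg <- (matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - polar$center_px[2]) *
    polar$spacing_mm[2]
  r <- sqrt(xg^2 + yg^2)
  th <- atan2(yg, xg) %% (2 * pi)
  n_a <- length(outer$radius_idx)
  # circular linear interpolation of the curves over angle
  a_pos <- th / polar$angular_step
  a0 <- floor(a_pos) %% n_a
  a1 <- (a0 + 1) %% n_a
  w <- a_pos - floor(a_pos)
  interp <- function(curve) {
    rmm <- boundary_radius_mm(curve)
    (1 - w) * rmm[a0 + 1] + w * rmm[a1 + 1]
  }
  r_out <- interp(outer)
  r_in <- interp(inner)
  if (all(r_out - r_in < polar$radial_step_mm / 2))
    stop("zero-width ring: boundaries leave no annulus to rasterise")
  r > r_in & r <= r_out
}
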