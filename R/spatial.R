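# Uniform-grid (cell list) spatial search.  Cells are cubes whose edge is
# the query radius, so any sphere of that radius is covered by the 27
# surrounding cells.  Pure R, vectorised over cells; linear in atom count.

build_grid <- function(xyz, cell) {
  stopifnot(cell > 0)
  origin <- if (nrow(xyz)) apply(xyz, 2, min) else c(0, 0, 0)
  idx <- floor(sweep(xyz, 2, origin) / cell)
  key <- paste(idx[, 1], idx[, 2], idx[, 3], sep = ",")
  list(cell = cell, origin = origin,
       bins = split(seq_len(nrow(xyz)), key), xyz = xyz)
}

grid_candidates <- function(grid, point) {
  centre <- floor((point - grid$origin) / grid$cell)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keys <- paste(centre[1] + offs[, 1], centre[2] + offs[, 2],
                centre[3] + offs[, 3], sep = ",")
  unlist(grid$bins[keys], use.names = FALSE)
}

#' Atoms within a radius of a probe point
#'
#' Grid-accelerated radius query over the atom table; returns exactly the
#' set a brute-force scan would, sorted by distance.
#'
#' @param atoms an `mg_structure`.
#' @param point numeric length-3 xyz probe, Angstrom.
#' @param radius search radius, Angstrom (> 0 for any hit; 0 returns an
#'   empty result).
#' @return tibble: the matching atom rows plus a `distance` column,
#'   ascending.
#' @examples
#' st <- make_fixture("ideal_6Ow")$atoms
#' neighbors(st, c(0, 0, 0), 2.3)
#' @export
neighbors <- function(atoms, point, radius) {
  stopifnot(length(point) == 3, is.finite(point), radius >= 0)
  empty <- dplyr::mutate(atoms[0, ], distance = double())
  if (radius == 0 || nrow(atoms) == 0L) return(tibble::as_tibble(empty))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  grid <- build_grid(xyz, radius)
  cand <- grid_candidates(grid, point)
  if (!length(cand)) return(tibble::as_tibble(empty))
  d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - point)^2))
  keep <- d <= radius
  out <- atoms[cand[keep], ]
  out$distance <- d[keep]
  tibble::as_tibble(out[order(out$distance), ])
}

# All unordered index pairs (i < j) within dmax, via half-shell cell walk.
# Returns tibble(i, j, distance).
pairs_within <- function(xyz, dmax) {
  n <- nrow(xyz)
  out0 <- tibble::tibble(i = integer(), j = integer(), distance = double())
  if (n < 2L || dmax <= 0) return(out0)
  grid <- build_grid(xyz, dmax)
  res_i <- list(); res_j <- list(); res_d <- list(); k <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  keys_of <- function(idx3, off) {
    paste(idx3[1] + off[1], idx3[2] + off[2], idx3[3] + off[3], sep = ",")
  }
  for (key in names(grid$bins)) {
    members <- grid$bins[[key]]
    idx3 <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    neigh_keys <- apply(offs, 1, keys_of, idx3 = idx3)
    cand <- unlist(grid$bins[neigh_keys], use.names = FALSE)
    for (i in members) {
      j <- cand[cand > i]
      if (!length(j)) next
      d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
      keep <- d <= dmax
      if (any(keep)) {
        k <- k + 1L
        res_i[[k]] <- rep.int(i, sum(keep))
        res_j[[k]] <- j[keep]
        res_d[[k]] <- d[keep]
      }
    }
  }
  if (k == 0L) return(out0)
  tibble::tibble(i = unlist(res_i), j = unlist(res_j), distance = unlist(res_d))
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Angle a-b-c at vertex b, degrees.
point_angle <- function(a, b, c) vec_angle(a - b, c - b)
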