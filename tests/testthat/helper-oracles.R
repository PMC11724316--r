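# Independent reference implementations used to cross-check the package:
# brute-force neighbour scans, 6!-assignment octahedral distortion, and a
# union-find for chain components.  These deliberately share no code with
# the implementation under test.

bf_neighbors <- function(atoms, point, radius) {
  d <- sqrt((atoms$x - point[1])^2 + (atoms$y - point[2])^2 +
              (atoms$z - point[3])^2)
  keep <- which(d <= radius & radius > 0)
  keep[order(d[keep])]
}

# Mean |deviation| from an ideal octahedron over all 720 vertex
# assignments; vertices are +/- the coordinate axes.
bf_distortion <- function(centre, ligand_xyz) {
  stopifnot(nrow(ligand_xyz) == 6)
  ang <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6) {
    u <- ligand_xyz[i, ] - centre
    v <- ligand_xyz[j, ] - centre
    cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    ang[i, j] <- ang[j, i] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  verts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  ideal <- matrix(90, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    if (all(verts[i, ] == -verts[j, ])) ideal[i, j] <- 180
  }
  perms <- gtools_permutations_6()
  ut <- upper.tri(ideal)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    dev <- mean(abs(ang[p, p][ut] - ideal[ut]))
    if (dev < best) best <- dev
  }
  best
}

# All permutations of 1:6, computed recursively (no external package).
gtools_permutations_6 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    perm_rec <- function(v) {
      if (length(v) == 1) return(matrix(v, 1, 1))
      out <- NULL
      for (k in seq_along(v)) {
        sub <- perm_rec(v[-k])
        out <- rbind(out, cbind(v[k], sub))
      }
      out
    }
    cache <<- perm_rec(1:6)
    cache
  }
})

# Union-find connected components over an edge list; returns the number
# of components among the touched vertices and a membership vector.
uf_components <- function(edges_a, edges_b) {
  verts <- sort(unique(c(edges_a, edges_b)))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[as.character(x)]] != x) {
      x <- parent[[as.character(x)]]
    }
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[as.character(ra)]] <- rb
  }
  roots <- vapply(verts, find, numeric(1))
  list(n = length(unique(roots)),
       membership = stats::setNames(roots, verts))
}

random_cloud <- function(n, box = 12, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    atom_id = seq_len(n), record = "ATOM", name = "O", altloc = "",
    residue_name = "HOH", chain_id = "S", residue_number = seq_len(n),
    icode = "", x = runif(n, 0, box), y = runif(n, 0, box),
    z = runif(n, 0, box), occupancy = 1, b_factor = 20, element = "O"
  )
}

# random rigid-body transform applied to an atom table
random_rigid <- function(atoms, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rot <- rx %*% ry %*% rz
  shift <- runif(3, -20, 20)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}

fixture_structure <- function(motif, ...) {
  assign_roles(make_fixture(motif, ...)$atoms)
}
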