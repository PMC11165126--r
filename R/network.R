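#' Construct a cluster network
#'
#' Holds the directed weighted adjacency of a small cluster, inter-node
#' distances, and the conduction-delay matrix derived from a signal velocity.
#' Matrix orientation: `W[k, j]` is the weight of the link j -> k (row =
#' target), matching the per-target sum over source nodes in the coupling
#' term of the dynamics.
#'
#' @param names ordered node labels.
#' @param W directed weight matrix, `W[k, j]` = weight of j -> k; non-negative
#'   with a zero diagonal.
#' @param D symmetric inter-node distance matrix (mm), zero diagonal.
#' @param velocity conduction speed (m/s); default 1, typical of short
#'   unmyelinated cortical pathways.  `delays[k, j] = D[k, j] / velocity`
#'   in ms-per-mm units, i.e. seconds when D is mm and velocity m/s * 1000:
#'   1 mm at 1 m/s is 1 ms.
#' @param coords optional node coordinate matrix (mm, rows = nodes), kept as
#'   metadata when distances were derived from coordinates.
#' @return an object of class `cluster_network` with derived `delays` (s).
#' @export
cluster_network <- function(names, W, D, velocity = 1, coords = NULL) {
  n <- length(names)
  W <- as.matrix(W); D <- as.matrix(D)
  if (!all(dim(W) == n) || !all(dim(D) == n))
    stop("W and D must be ", n, "x", n, " matrices", call. = FALSE)
  if (any(W < 0)) stop("link weights must be non-negative", call. = FALSE)
  if (any(diag(W) != 0)) stop("W must have a zero diagonal (no self-links)",
                              call. = FALSE)
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  if (any(diag(D) != 0)) stop("D must have a zero diagonal", call. = FALSE)
  if (any(D[W > 0] <= 0))
    stop("every present link needs a positive inter-node distance", call. = FALSE)
  if (!is.numeric(velocity) || velocity <= 0)
    stop("velocity must be positive (use Inf for instantaneous coupling)",
         call. = FALSE)
  dimnames(W) <- dimnames(D) <- list(names, names)
  # D in mm, velocity in m/s: d/v in ms, /1000 -> seconds
  delays <- (D / velocity) / 1000
  structure(list(names = names, W = W, D = D, velocity = velocity,
                 delays = delays, coords = coords),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf("<cluster_network> %d nodes: %s\n", length(x$names),
              paste(x$names, collapse = ", ")))
  cat(sprintf("  %d directed links, weights %.0f-%.0f, max distance %.2f mm, v = %g m/s\n",
              sum(x$W > 0), min(x$W[x$W > 0]), max(x$W),
              max(x$D), x$velocity))
  invisible(x)
}

#' Conduction delays in integrator steps
#'
#' Rounds each link delay to the nearest integer number of steps of size `dt`.
#' The maximum entry sets the required depth of the delayed-output history
#' buffer.
#'
#' @param net a [cluster_network()].
#' @param dt integrator step (s).
#' @return integer matrix of step delays, same orientation as `net$W`.
#' @export
#' @examples
#' # 3.4 mm at 1 m/s with dt = 0.1 ms is 34 steps
delay_steps <- function(net, dt) {
  stopifnot(inherits(net, "cluster_network"), dt > 0)
  s <- round(net$delays / dt)
  mode(s) <- "integer"
  s
}

#' Read a cluster network from edge-list and coordinate/distance files
#'
#' @param edges data frame or CSV path with columns `source,target,weight`.
#' @param coords data frame or CSV path with columns `node,x_mm,y_mm,z_mm`;
#'   distances are Euclidean.  Give either `coords` or `distances`.
#' @param distances data frame or CSV path holding a square distance matrix
#'   (mm) with node names as header row and first column.
#' @param velocity conduction speed (m/s).
#' @return a [cluster_network()].  Node ordering follows the order of first
#'   appearance in the coordinate (or distance) input.
#' @details Duplicate `(source, target)` rows and self-edges are rejected
#'   rather than silently merged.
#' @export
load_edge_list <- function(edges, coords = NULL, distances = NULL,
                           velocity = 1) {
  read_maybe <- function(x) if (is.character(x)) read.csv(x, check.names = FALSE) else x
  edges <- read_maybe(edges)
  if (!all(c("source", "target", "weight") %in% names(edges)))
    stop("edge input needs columns source, target, weight", call. = FALSE)
  if (is.null(coords) == is.null(distances))
    stop("give exactly one of 'coords' or 'distances'", call. = FALSE)

  if (!is.null(coords)) {
    coords <- read_maybe(coords)
    if (!all(c("node", "x_mm", "y_mm", "z_mm") %in% names(coords)))
      stop("coordinate input needs columns node, x_mm, y_mm, z_mm", call. = FALSE)
    nodes <- as.character(coords$node)
    xyz <- as.matrix(coords[, c("x_mm", "y_mm", "z_mm")])
    rownames(xyz) <- nodes
    D <- as.matrix(stats::dist(xyz))
  } else {
    dm <- read_maybe(distances)
    nodes <- as.character(dm[[1]])
    D <- as.matrix(dm[, -1, drop = FALSE])
    if (!identical(colnames(D), nodes))
      stop("distance matrix header row and first column disagree", call. = FALSE)
    if (any(abs(D - t(D)) > 1e-9))
      stop("distance input is not symmetric", call. = FALSE)
    rownames(D) <- nodes
    xyz <- NULL
  }

  n <- length(nodes)
  src <- as.character(edges$source); tgt <- as.character(edges$target)
  bad <- !(src %in% nodes) | !(tgt %in% nodes)
  if (any(bad))
    stop("edge row(s) with unknown node names: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (any(edges$weight < 0)) {
    i <- which(edges$weight < 0)[1]
    stop("negative weight in edge row ", i, call. = FALSE)
  }
  if (any(src == tgt)) {
    i <- which(src == tgt)[1]
    stop("self-edge in row ", i, " (", src[i], ")", call. = FALSE)
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate edge (", src[i], " -> ", tgt[i], ") in row ", i,
         call. = FALSE)
  }
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[cbind(match(tgt, nodes), match(src, nodes))] <- edges$weight
  cluster_network(nodes, W, D[nodes, nodes], velocity = velocity, coords = xyz)
}

#' Write a cluster network to edge-list and coordinate CSV files
#'
#' Inverse of [load_edge_list()]; round-trips `W` and `D` exactly when the
#' network carries coordinates.
#'
#' @param net a [cluster_network()].
#' @param edge_file,coord_file output CSV paths.
#' @return invisibly, the two file paths.
#' @export
write_edge_list <- function(net, edge_file, coord_file) {
  stopifnot(inherits(net, "cluster_network"))
  idx <- which(net$W > 0, arr.ind = TRUE)
  ed <- data.frame(source = net$names[idx[, 2]],
                   target = net$names[idx[, 1]],
                   weight = net$W[idx])
  ed <- ed[order(ed$source, ed$target), ]
  write.csv(ed, edge_file, row.names = FALSE, quote = FALSE)
  if (is.null(net$coords))
    stop("network carries no coordinates; write the distance matrix instead",
         call. = FALSE)
  co <- data.frame(node = net$names,
                   x_mm = net$coords[, 1], y_mm = net$coords[, 2],
                   z_mm = net$coords[, 3])
  write.csv(co, coord_file, row.names = FALSE, quote = FALSE)
  invisible(c(edge_file, coord_file))
}

#' Synthetic prefrontal-like six-node cluster
#'
#' Generates a weighted directed connectome with the statistical signature of
#' the compact six-area prefrontal cluster (A10, A32V, A32, A9, A46D, A11):
#' 29 of the 30 possible directed links present (the missing pair drawn at
#' random), a heavy-tailed weight distribution in which at least one third of
#' links exceed weight 1000 and at least another quarter exceed 500, and a
#' square-pyramid geometry with A10 apical and every node within 3.4 mm of
#' A10.  The true tracer-derived weight matrix is not public; this fixture
#' emulates its reported statistics only.
#'
#' @param seed integer seed; the same seed yields bit-identical networks.
#' @param velocity conduction speed (m/s), default 1.
#' @param radius maximum distance (mm) of any node from A10, default 3.4.
#' @return a [cluster_network()].
#' @export
#' @examples
#' net <- make_pfc_fixture(1)
#' validate_network(net)$ok
make_pfc_fixture <- function(seed = 1, velocity = 1, radius = 3.4) {
  nodes <- c("A10", "A32V", "A32", "A9", "A46D", "A11")
  n <- 6L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # 29 of 30 off-diagonal links; the single absent pair is uniform per seed
  pairs <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
  absent <- sample(nrow(pairs), 1)
  present <- pairs[-absent, , drop = FALSE]
  m <- nrow(present)  # 29

  # heavy-tailed draw, then rank adjustment pinning the tail fractions:
  # top ceiling(m/3) links > 1000, next ceiling(m/4) in (500, 1000]
  w <- sort(stats::rlnorm(m, meanlog = 6.0, sdlog = 1.1), decreasing = TRUE)
  n1 <- ceiling(m / 3); n2 <- ceiling(m / 4)
  w[seq_len(n1)] <- 1000 * (1 + sort(stats::rexp(n1, rate = 1.2),
                                     decreasing = TRUE))
  w[n1 + seq_len(n2)] <- sort(runif(n2, 501, 1000), decreasing = TRUE)
  lo <- w[-seq_len(n1 + n2)]
  w[-seq_len(n1 + n2)] <- pmin(lo, 500 * exp(-runif(length(lo), 0.01, 2)))
  w <- round(w, 1)  # sorted, strongest first
  # hub structure: A10 (node 1) is the out-hub, A32V (node 2) the in-hub and
  # A11 (node 6) a marginal in-hub; strongest weights go to their links,
  # with seeded jitter so the assignment varies between seeds
  score <- 3 * (present[, 2] == 1) + 2 * (present[, 1] == 2) +
    1 * (present[, 1] == 6) + stats::rnorm(m, 0, 1.2)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[present[order(score, decreasing = TRUE), , drop = FALSE]] <- w

  # square pyramid, A10 apical; jittered, then scaled inside the radius
  base <- rbind(c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
                c( 0,  0, -0.6))
  apex <- c(0, 0, 1.4)
  xyz <- rbind(apex, base * 1.6) + matrix(stats::rnorm(18, 0, 0.25), 6, 3)
  xyz[1, ] <- apex  # keep the hub at the apex
  xyz <- sweep(xyz, 2, xyz[1, ])  # A10 at the origin
  scale <- radius * runif(1, 0.93, 0.995) / max(sqrt(rowSums(xyz^2)))
  xyz <- xyz * scale
  rownames(xyz) <- nodes
  colnames(xyz) <- c("x_mm", "y_mm", "z_mm")
  D <- as.matrix(stats::dist(xyz))

  cluster_network(nodes, W, D, velocity = velocity, coords = xyz)
}

# save/restore the global RNG state so fixture generation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Validate a cluster network
#'
#' Report-only checker: non-negativity and zero diagonal of `W`, symmetry of
#' `D`, exact delay derivation, and summary statistics (link count, weight
#' quantiles, maximum distance).
#'
#' @param net a [cluster_network()].
#' @param dt optional integrator step (s); when given, also reports the step
#'   delays implied by `dt`.
#' @return a list with per-check logicals under `checks`, overall `ok`, and
#'   `stats`.
#' @export
validate_network <- function(net, dt = NULL) {
  checks <- list(
    weights_nonnegative = all(net$W >= 0),
    zero_diagonal_W = all(diag(net$W) == 0),
    distance_symmetric = all(abs(net$D - t(net$D)) <= 1e-9),
    zero_diagonal_D = all(diag(net$D) == 0),
    links_have_distance = all(net$D[net$W > 0] > 0),
    delays_consistent = all(abs(net$delays - (net$D / net$velocity) / 1000) <=
                              1e-12))
  w <- net$W[net$W > 0]
  stats <- list(n_links = length(w),
                weight_quantiles = quantile(w, c(0, 0.25, 0.5, 0.75, 1)),
                frac_gt_1000 = mean(w > 1000),
                frac_gt_500 = mean(w > 500),
                max_distance_mm = max(net$D),
                max_dist_from_first_mm = max(net$D[1, ]))
  if (!is.null(dt)) stats$max_delay_steps <- max(delay_steps(net, dt))
  list(ok = all(unlist(checks)), checks = checks, stats = stats)
}
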