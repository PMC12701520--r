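#' Build a mesh graph
#'
#' Desk-scale stand-in for cortical surface meshes / voxel lattices: an
#' undirected connected graph on which vertex-wise statistics and TFCE are
#' computed. Topologies: `"grid"` (near-square 2-D lattice), `"ring"`, or
#' `"random"` (Erdos-Renyi with components joined deterministically to
#' guarantee connectivity).
#'
#' @param n_vertices number of vertices (>= 1).
#' @param topology `"grid"`, `"ring"` or `"random"`.
#' @param seed integer seed (used by `"random"` only).
#' @return an object of class `mesh_graph`: list with `n_vertices` and a
#'   two-column integer `edges` matrix (1-based, `from < to`).
#' @export
make_mesh <- function(n_vertices, topology = c("grid", "ring", "random"),
                      seed = 1) {
  if (!is.numeric(n_vertices) || n_vertices < 1) {
    stop_lateq("n_vertices must be >= 1")
  }
  n <- as.integer(n_vertices)
  topology <- match.arg(topology)
  g <- switch(topology,
    grid = {
      r <- max(1L, floor(sqrt(n)))
      while (n %% r != 0L) r <- r - 1L
      igraph::make_lattice(c(r, n %/% r))
    },
    ring = if (n == 1L) igraph::make_empty_graph(1, directed = FALSE)
           else if (n == 2L) igraph::make_graph(c(1, 2), directed = FALSE)
           else igraph::make_ring(n),
    random = {
      set_seed_strict(derive_seed(seed, "mesh"))
      gr <- igraph::sample_gnp(n, p = min(1, 2 * log(max(n, 2)) / max(n, 2)))
      comp <- igraph::components(gr)
      if (comp$no > 1L) {
        anchors <- vapply(seq_len(comp$no),
                          function(k) which(comp$membership == k)[1], 1L)
        gr <- igraph::add_edges(gr, as.vector(rbind(anchors[-length(anchors)],
                                                    anchors[-1])))
      }
      igraph::simplify(gr)
    })
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  structure(list(n_vertices = n, edges = edges), class = "mesh_graph")
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("<mesh_graph> %d vertices, %d edges\n",
              x$n_vertices, nrow(x$edges)))
  invisible(x)
}

mesh_to_igraph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, mesh$n_vertices -
                               max(c(0L, as.vector(mesh$edges)))))
}

validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_graph"))
  e <- mesh$edges
  if (nrow(e) && (any(e < 1) || any(e > mesh$n_vertices))) {
    stop_lateq("mesh edges reference vertices outside [1, n_vertices]")
  }
  if (nrow(e) && any(e[, 1] == e[, 2])) {
    stop_lateq("mesh contains self-loops")
  }
  invisible(mesh)
}

#' Generate cross-sectional vertex data on a mesh
#'
#' Simulates a subjects x vertices matrix
#' `data = baseline + indicator(group 2) * effect_map + covariate terms +
#' N(0, noise_sd^2)`.
#'
#' @param mesh a [make_mesh()] graph.
#' @param groups character/factor vector of group labels (one per subject).
#' @param effect_map per-vertex additive effect for the second group level.
#' @param noise_sd residual SD.
#' @param seed integer seed.
#' @param baseline scalar baseline level (thickness-like, mm).
#' @param covariates optional data frame of numeric subject covariates.
#' @param covariate_effects named list: for each covariate, a per-vertex
#'   effect vector (units per covariate unit).
#' @return list with `data` (subjects x vertices matrix) and `design`
#'   (data frame with `group` and the covariates).
#' @export
generate_mesh_data <- function(mesh, groups, effect_map, noise_sd, seed = 1,
                               baseline = 2.8, covariates = NULL,
                               covariate_effects = NULL) {
  validate_mesh(mesh)
  if (length(effect_map) != mesh$n_vertices) {
    stop_lateq("effect_map length (%d) != vertex count (%d)",
               length(effect_map), mesh$n_vertices)
  }
  groups <- factor(groups)
  n <- length(groups)
  set_seed_strict(derive_seed(seed, "mesh_data"))
  ind <- as.numeric(groups == levels(groups)[min(2, nlevels(groups))])
  data <- baseline + outer(ind, effect_map)
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      eff <- covariate_effects[[nm]]
      if (is.null(eff)) next
      if (length(eff) != mesh$n_vertices) {
        stop_lateq("covariate effect '%s' length mismatch", nm)
      }
      data <- data + outer(covariates[[nm]], eff)
    }
  }
  data <- data + matrix(rnorm(n * mesh$n_vertices, 0, noise_sd),
                        n, mesh$n_vertices)
  design <- data.frame(group = groups)
  if (!is.null(covariates)) design <- cbind(design, covariates)
  list(data = data, design = design)
}

#' Generate longitudinal vertex data on a mesh
#'
#' Per-vertex longitudinal model with a planted time x group slope
#' difference: `y = baseline + b0_i + time * (base_slope +
#' indicator(group 2) * slope_map) + N(0, noise_sd^2)`.
#'
#' @inheritParams generate_mesh_data
#' @param slope_map per-vertex additional atrophy slope (units/year) in the
#'   second group level.
#' @param times visit times in years (same schedule for all subjects).
#' @param base_slope common slope (units/year).
#' @param re_intercept_sd subject random-intercept SD.
#' @return list with `data` (visits x vertices matrix) and `meta`
#'   (data frame: `subject_id`, `time`, `group`, `age`).
#' @export
generate_mesh_data_long <- function(mesh, groups, slope_map, times,
                                    noise_sd, seed = 1, baseline = 2.8,
                                    base_slope = -0.02,
                                    re_intercept_sd = 0.1) {
  validate_mesh(mesh)
  if (length(slope_map) != mesh$n_vertices) {
    stop_lateq("slope_map length (%d) != vertex count (%d)",
               length(slope_map), mesh$n_vertices)
  }
  groups <- factor(groups)
  n <- length(groups)
  set_seed_strict(derive_seed(seed, "mesh_data_long"))
  b0 <- rnorm(n, 0, re_intercept_sd)
  age0 <- rnorm(n, 75, 7)
  idx <- rep(seq_len(n), each = length(times))
  tt <- rep(times, times = n)
  ind <- as.numeric(groups == levels(groups)[min(2, nlevels(groups))])
  mu <- baseline + b0[idx] +
    tt * base_slope + outer(tt * ind[idx], slope_map)
  data <- mu + matrix(rnorm(length(idx) * mesh$n_vertices, 0, noise_sd),
                      length(idx), mesh$n_vertices)
  meta <- data.frame(
    subject_id = sprintf("M%04d", idx),
    time = tt,
    group = groups[idx],
    age = age0[idx],
    stringsAsFactors = FALSE)
  list(data = data, meta = meta)
}
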