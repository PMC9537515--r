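# Bootstrap model averaging, arc-strength thresholding, Markov blankets and
# local linear models.
#
# Arc strength of an unordered pair is the fraction of bootstrap replicates
# whose learned DAG contains the edge in either direction; the direction
# probability of an orientation is the fraction of those edge-containing
# replicates oriented that way. Thresholding keeps pairs with strength
# strictly above the cutoff, orients each by majority direction, and breaks
# any residual cycle by dropping its weakest arc, yielding a fully directed
# acyclic network.

#' Bootstrap arc strengths and direction probabilities
#'
#' Resamples rows (countries) with replacement `n_boot` times, learns a DAG
#' on each replicate with [hill_climb()], and averages: for every unordered
#' pair, `strength` is the fraction of replicates containing the edge in
#' either direction; `direction_probability` is the fraction of
#' edge-containing replicates oriented `from -> to`. Rows are reported in
#' the majority orientation (ties oriented from the earlier data column).
#'
#' @inheritParams hill_climb
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param seed Integer seed making the resampling reproducible.
#' @return A `hen_arc_strength` tibble `from`, `to`, `strength`,
#'   `direction_probability`, carrying `n_boot`, the node set, and the full
#'   matrix of per-direction replicate counts (`direction_counts`) as
#'   attributes.
#' @export
bootstrap_arcs <- function(data, blacklist = NULL, n_boot = 200, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  data <- as.data.frame(data)
  nodes <- colnames(data)
  p <- length(nodes)
  counts <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  run <- function() {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      dag <- hill_climb(data[idx, , drop = FALSE], blacklist = blacklist)
      counts <<- counts + dag$amat
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())

  either <- counts + t(counts)
  idx <- which(upper.tri(either) & either > 0, arr.ind = TRUE)
  rows <- purrr::map_dfr(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    # i < j by upper.tri: lexicographic tie goes i -> j
    fwd <- counts[i, j] >= counts[j, i]
    from <- if (fwd) i else j
    to <- if (fwd) j else i
    tibble(
      from = nodes[from], to = nodes[to],
      strength = either[i, j] / n_boot,
      direction_probability = counts[from, to] / either[i, j]
    )
  })
  if (!nrow(rows)) {
    rows <- tibble(
      from = character(), to = character(),
      strength = numeric(), direction_probability = numeric()
    )
  }
  rows <- arrange(rows, dplyr::desc(.data$strength), .data$from, .data$to)
  structure(rows,
    nodes = nodes, n_boot = n_boot, direction_counts = counts,
    class = c("hen_arc_strength", class(rows))
  )
}

find_cycle <- function(amat) {
  # returns the arcs of one directed cycle as an index matrix, or NULL
  p <- nrow(amat)
  color <- integer(p) # 0 white, 1 grey, 2 black
  parent <- integer(p)
  cyc <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (w in which(amat[v, ])) {
      if (!is.null(cyc)) {
        return()
      }
      if (color[w] == 1L) {
        path <- v
        u <- v
        while (u != w) {
          u <- parent[u]
          path <- c(path, u)
        }
        path <- rev(path)
        cyc <<- cbind(path, c(path[-1], path[1]))
        return()
      }
      if (color[w] == 0L) {
        parent[w] <<- v
        visit(w)
      }
    }
    color[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L && is.null(cyc)) visit(v)
  }
  cyc
}

#' Threshold averaged arc strengths into a directed network
#'
#' Keeps arcs with `strength > min_strength`, orients each retained pair by
#' its majority direction probability, and -- should majority orientations
#' ever form a cycle -- repeatedly drops the weakest arc of a cycle until
#' the graph is acyclic. The empirical distribution of all arc strengths is
#' attached for threshold diagnostics (the curve one inspects to choose the
#' cutoff).
#'
#' @param strengths A `hen_arc_strength` table from [bootstrap_arcs()].
#' @param min_strength Retention cutoff on arc strength (default 0.6,
#'   exclusive).
#' @return A `hen_network`: nodes, arcs tibble (`from`, `to`, `strength`,
#'   `direction_probability`), adjacency matrix, and the strength curve.
#' @export
threshold_network <- function(strengths, min_strength = 0.6) {
  stopifnot(min_strength >= 0, min_strength <= 1)
  nodes <- attr(strengths, "nodes")
  curve <- tibble(strength = sort(strengths$strength)) |>
    mutate(cumulative_fraction = dplyr::row_number() / dplyr::n())
  kept <- filter(as_tibble(strengths), .data$strength > min_strength)
  p <- length(nodes)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (nrow(kept)) {
    amat[cbind(match(kept$from, nodes), match(kept$to, nodes))] <- TRUE
  }
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(kept)) {
    w[cbind(match(kept$from, nodes), match(kept$to, nodes))] <- kept$strength
  }
  dropped <- 0L
  repeat {
    cyc <- find_cycle(amat)
    if (is.null(cyc)) break
    ws <- w[cyc]
    weakest <- cyc[which.min(ws), , drop = FALSE]
    amat[weakest] <- FALSE
    dropped <- dropped + 1L
  }
  idx <- which(amat, arr.ind = TRUE)
  arcs <- kept[match(
    paste(nodes[idx[, 1]], nodes[idx[, 2]]),
    paste(kept$from, kept$to)
  ), ] |> arrange(.data$from, .data$to)
  net <- structure(
    list(
      nodes = nodes, arcs = arcs, amat = amat,
      min_strength = min_strength, strength_curve = curve,
      n_cycle_arcs_dropped = dropped
    ),
    class = "hen_network"
  )
  net
}

#' @export
print.hen_network <- function(x, ...) {
  g <- glance(x)
  cat("<hen_network> ", g$n_nodes, " nodes, ", g$n_edges,
    " arcs (strength > ", x$min_strength, "), mean Markov blanket ",
    round(g$mean_markov_blanket_size, 2), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.hen_network <- function(x, ...) x$arcs

#' Summary statistics of a directed network
#'
#' One-row tibble with node count, arc count and the mean Markov-blanket
#' size over nodes.
#'
#' @param x A `hen_network` (or `hen_dag`).
#' @param ... Unused.
#' @return A tibble with columns `n_nodes`, `n_edges`,
#'   `mean_markov_blanket_size`.
#' @export
glance.hen_network <- function(x, ...) {
  mb_sizes <- vapply(x$nodes, function(v) length(markov_blanket(x, v)), numeric(1))
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$arcs),
    mean_markov_blanket_size = if (length(mb_sizes)) mean(mb_sizes) else 0
  )
}

#' @export
glance.hen_dag <- function(x, ...) {
  glance.hen_network(x, ...)
}

#' Markov blanket of a node
#'
#' Parents, children, and other parents of the node's children (the minimal
#' set rendering the node conditionally independent of the remainder).
#'
#' @param network A `hen_network` or `hen_dag`.
#' @param node Node name.
#' @return Character vector of blanket members, sorted.
#' @export
markov_blanket <- function(network, node) {
  nodes <- network$nodes
  if (!node %in% nodes) stop("unknown node: ", node)
  amat <- network$amat
  j <- match(node, nodes)
  parents <- which(amat[, j])
  children <- which(amat[j, ])
  spouses <- if (length(children)) which(rowSums(amat[, children, drop = FALSE]) > 0) else integer()
  sort(setdiff(nodes[union(union(parents, children), spouses)], node))
}

#' Fit local linear models for every node of a network
#'
#' Ordinary least squares (via [stats::lm()]) of each node on its parents in
#' the network, on the original (unstandardised) data: the linear
#' relationships and standard errors the averaged network implies.
#'
#' @param network A `hen_network` or `hen_dag`.
#' @param data The data the network was learned from (original scale).
#' @return A `hen_local_fits` tibble: `node`, `term` (`"(Intercept)"` or a
#'   parent), `estimate`, `std_error`, `residual_variance`.
#' @export
fit_local_models <- function(network, data) {
  data <- as.data.frame(data)
  stopifnot(all(network$nodes %in% colnames(data)))
  fits <- purrr::map_dfr(network$nodes, function(v) {
    parents <- network$nodes[which(network$amat[, v])]
    if (length(parents) >= nrow(data)) {
      stop("degeneracy error: node ", v, " has more parents than observations")
    }
    fml <- stats::reformulate(
      if (length(parents)) paste0("`", parents, "`") else "1",
      response = paste0("`", v, "`")
    )
    fit <- stats::lm(fml, data = data)
    sm <- summary(fit)
    co <- sm$coefficients
    tibble(
      node = v,
      term = gsub("`", "", rownames(co)),
      estimate = unname(co[, "Estimate"]),
      std_error = unname(co[, "Std. Error"]),
      residual_variance = sm$sigma^2
    )
  })
  structure(fits, class = c("hen_local_fits", class(fits)))
}

#' Write a network to Graphviz DOT format
#'
#' @param network A `hen_network` or `hen_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(network, path) {
  arcs <- network$arcs
  lab <- if ("strength" %in% names(arcs)) {
    sprintf(" [label=\"%.2f\"]", arcs$strength)
  } else {
    rep("", nrow(arcs))
  }
  lines <- c(
    "digraph hennet {",
    sprintf("  \"%s\";", network$nodes),
    sprintf("  \"%s\" -> \"%s\"%s;", arcs$from, arcs$to, lab),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
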