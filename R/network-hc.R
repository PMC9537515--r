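# Blacklist-constrained hill climbing over DAGs, plus the exhaustive-search
# oracle for small problems.
#
# The search state is a logical adjacency matrix (amat[i, j] = TRUE means
# i -> j). Each iteration evaluates every candidate single-arc addition,
# deletion and reversal and applies the highest-gain strictly improving
# move; ties break lexicographically on (operation, from, to) with nodes
# ordered as data columns, so the search is deterministic. Because the
# score is decomposable, a move only re-scores the one or two nodes whose
# parent sets change, and local scores are memoised per (node, parent set).

amat_parents <- function(amat, j) which(amat[, j])

# would adding from -> to create a cycle? (i.e. is `from` reachable from `to`)
creates_cycle <- function(amat, from, to) {
  if (from == to) {
    return(TRUE)
  }
  seen <- logical(nrow(amat))
  stack <- to
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == from) {
      return(TRUE)
    }
    if (!seen[v]) {
      seen[v] <- TRUE
      stack <- c(stack, which(amat[v, ] & !seen))
    }
  }
  FALSE
}

blacklist_matrix <- function(blacklist, nodes) {
  p <- length(nodes)
  bl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(blacklist) && nrow(as.data.frame(blacklist))) {
    blacklist <- as_tibble(blacklist)
    stopifnot(all(c("from", "to") %in% names(blacklist)))
    unknown <- setdiff(c(blacklist$from, blacklist$to), nodes)
    if (length(unknown)) {
      stop("blacklist names absent from data: ", paste(utils::head(unknown, 5L), collapse = ", "))
    }
    bl[cbind(match(blacklist$from, nodes), match(blacklist$to, nodes))] <- TRUE
  }
  bl
}

# undirected maximum spanning tree of |correlation|, oriented from lower to
# higher column index (always acyclic); blacklisted orientations flip, and
# edges forbidden in both directions are dropped. A deterministic warm
# start that seeds the climb with the strongest dependencies already
# conditioned as tree edges.
correlation_tree_start <- function(x, bl) {
  p <- ncol(x)
  nodes <- colnames(x)
  C <- abs(stats::cor(x))
  diag(C) <- 0
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  in_tree <- 1L
  while (length(in_tree) < p) {
    out <- setdiff(seq_len(p), in_tree)
    sub <- C[in_tree, out, drop = FALSE]
    k <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- in_tree[k[1]]
    j <- out[k[2]]
    from <- min(i, j)
    to <- max(i, j)
    if (bl[from, to]) {
      from <- max(i, j)
      to <- min(i, j)
    }
    if (!bl[from, to]) amat[from, to] <- TRUE
    in_tree <- c(in_tree, j)
  }
  amat
}

new_hen_dag <- function(amat, nodes, score, n) {
  idx <- which(amat, arr.ind = TRUE)
  arcs <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]]) |>
    arrange(.data$from, .data$to)
  structure(
    list(nodes = nodes, amat = amat, arcs = arcs, score = score, n = n),
    class = "hen_dag"
  )
}

#' @export
print.hen_dag <- function(x, ...) {
  cat("<hen_dag> ", length(x$nodes), " nodes, ", nrow(x$arcs),
    " arcs, BIC score ", format(x$score), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.hen_dag <- function(x, ...) x$arcs

#' Learn a DAG by score-based hill climbing
#'
#' Greedy search over directed acyclic graphs maximising the decomposable
#' Gaussian BIC score (see [local_score()]). Starting from the empty graph,
#' every candidate single-arc addition, deletion and reversal is evaluated
#' each iteration and the highest-gain strictly improving move is applied,
#' with ties broken in lexicographic (operation, from, to) order -- nodes
#' ordered as the data columns -- so the result is deterministic for fixed
#' data. The search stops at a single-move local optimum. Columns are
#' standardised before scoring.
#'
#' Two deterministic starting points are climbed -- the empty graph and a
#' maximum |correlation| spanning tree oriented by column order -- and the
#' higher-scoring local optimum is returned; greedy ascent from the empty
#' graph alone is prone to locking in marginal-correlation shortcut arcs on
#' strongly autocorrelated systems. Each climb follows greedy ascent with a
#' bounded tabu phase (best non-improving moves are taken while recently
#' applied moves may not be undone, remembering the best graph seen) and a
#' final greedy polish, so the returned graph is always a single-move local
#' optimum.
#'
#' @param data Data frame or matrix of numeric columns.
#' @param blacklist Optional data frame `from`, `to` of forbidden arcs
#'   (forbidden in that direction only).
#' @param tol Minimum score improvement for a move to count as improving.
#' @param starts Warm starts to climb from: any subset of
#'   `c("empty", "tree")`.
#' @return A `hen_dag`: nodes, adjacency matrix, arcs tibble, total score.
#' @export
hill_climb <- function(data, blacklist = NULL, tol = 1e-6,
                       starts = c("empty", "tree")) {
  starts <- match.arg(starts, several.ok = TRUE)
  x <- standardize_columns(data)
  nodes <- colnames(x)
  p <- length(nodes)
  n <- nrow(x)
  if (n <= 3) stop("need more than 3 observations")
  bl <- blacklist_matrix(blacklist, nodes)
  cache <- new_score_cache(mle_cov(x), n)

  best <- NULL
  for (start in starts) {
    amat <- if (start == "empty" || p < 2) {
      matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    } else {
      correlation_tree_start(x, bl)
    }
    res <- climb_from(amat, cache, bl, p, tol)
    if (is.null(best) || res$score > best$score) best <- res
  }
  new_hen_dag(best$amat, nodes, best$score, n)
}

# score gains of every single-arc addition and deletion, batched per child
# from one Cholesky factor of the parent covariance block.
#
# Addition of candidate x to child j (rank-one update):
#   s2(P + x) = s2(P) - pcov(x, j | P)^2 / pvar(x | P)
# Deletion of parent x of child j (rank-one downdate, with A = S_PP^-1 and
# regression coefficients b = A S_Pj):
#   s2(P - x) = s2(P) + b_x^2 / A_xx
# Pairs that are not legal moves are -Inf in `add` / NA in `del`; the scan
# applies arc-existence, blacklist and acyclicity constraints on top.
move_delta_matrices <- function(amat, cache, p) {
  S <- cache$S
  n <- cache$n
  add <- matrix(-Inf, p, p)
  del <- matrix(NA_real_, p, p)
  dS <- diag(S)
  half_log_n <- log(n) / 2
  for (j in seq_len(p)) {
    P <- which(amat[, j])
    k <- length(P)
    if (k == 0L) {
      s2P <- S[j, j]
      num <- S[, j]
      den <- dS
    } else {
      ch <- tryCatch(chol(S[P, P, drop = FALSE]), error = function(e) NULL)
      if (is.null(ch)) next
      A <- chol2inv(ch)
      SPj <- S[P, j]
      b <- as.vector(A %*% SPj)
      s2P <- S[j, j] - sum(b * SPj)
      if (!is.finite(s2P) || s2P < 1e-12) next
      M <- S[, P, drop = FALSE] %*% A # p x k
      num <- S[, j] - as.vector(M %*% SPj)
      den <- dS - rowSums(M * S[, P, drop = FALSE])
      s2_drop <- s2P + b^2 / diag(A)
      del[P, j] <- -n / 2 * (log(s2_drop) - log(s2P)) + half_log_n
    }
    if (!is.finite(s2P) || s2P < 1e-12) next
    ok <- den > 1e-12
    s2new <- rep(-1, p)
    s2new[ok] <- s2P - num[ok]^2 / den[ok]
    # stricter than the 1e-12 scoring guard so a proposed addition can never
    # land on a parent set the exact scorer then rejects as degenerate
    good <- ok & s2new > 1e-10
    delta <- rep(-Inf, p)
    delta[good] <- -n / 2 * (log(s2new[good]) - log(s2P)) - half_log_n
    delta[j] <- -Inf
    if (k) delta[P] <- -Inf
    add[, j] <- delta
  }
  list(add = add, del = del)
}

# one full scan of the move neighbourhood; returns the best admissible move
# (NULL if none beats min_delta). `forbidden` is a character set of move keys
# (tabu list); ties keep the first candidate in (operation, from, to) order.
best_move_scan <- function(amat, cache, bl, p, local, min_delta, forbidden = character()) {
  best_delta <- min_delta
  best_move <- NULL
  dm <- move_delta_matrices(amat, cache, p)
  has_tabu <- length(forbidden) > 0L
  arcs <- which(amat, arr.ind = TRUE)
  arcs <- arcs[order(arcs[, 1], arcs[, 2]), , drop = FALSE]
  # additions
  for (from in seq_len(p)) {
    for (to in seq_len(p)) {
      delta <- dm$add[from, to]
      if (delta <= best_delta) next
      if (amat[from, to] || amat[to, from] || bl[from, to]) next
      if (has_tabu && paste0("add|", from, "|", to) %in% forbidden) next
      if (creates_cycle(amat, from, to)) next
      best_delta <- delta
      best_move <- list(op = "add", from = from, to = to, delta = delta)
    }
  }
  # deletions
  for (a in seq_len(nrow(arcs))) {
    from <- arcs[a, 1]
    to <- arcs[a, 2]
    delta <- dm$del[from, to]
    if (is.na(delta) || delta <= best_delta) next
    if (has_tabu && paste0("delete|", from, "|", to) %in% forbidden) next
    best_delta <- delta
    best_move <- list(op = "delete", from = from, to = to, delta = delta)
  }
  # reversals: score gain is delete(from -> to) plus add(to -> from)
  for (a in seq_len(nrow(arcs))) {
    from <- arcs[a, 1]
    to <- arcs[a, 2]
    if (bl[to, from]) next
    d_add <- dm$add[to, from]
    d_del <- dm$del[from, to]
    if (is.na(d_del) || !is.finite(d_add)) next
    delta <- d_del + d_add
    if (delta <= best_delta) next
    if (has_tabu && paste0("reverse|", from, "|", to) %in% forbidden) next
    amat[from, to] <- FALSE
    cyc <- creates_cycle(amat, to, from)
    amat[from, to] <- TRUE
    if (cyc) next
    best_delta <- delta
    best_move <- list(op = "reverse", from = from, to = to, delta = delta)
  }
  best_move
}

apply_move <- function(amat, cache, local, move) {
  if (move$op == "add") {
    amat[move$from, move$to] <- TRUE
  } else if (move$op == "delete") {
    amat[move$from, move$to] <- FALSE
  } else {
    amat[move$from, move$to] <- FALSE
    amat[move$to, move$from] <- TRUE
    local[move$from] <- cached_score(cache, move$from, amat_parents(amat, move$from))
  }
  local[move$to] <- cached_score(cache, move$to, amat_parents(amat, move$to))
  list(amat = amat, local = local)
}

# the inverse action, forbidden while the move sits on the tabu list
inverse_move_key <- function(move) {
  switch(move$op,
    add = paste0("delete|", move$from, "|", move$to),
    delete = paste0("add|", move$from, "|", move$to),
    reverse = paste0("reverse|", move$to, "|", move$from)
  )
}

climb_from <- function(amat, cache, bl, p, tol, tabu_len = 10L, max_stall = 15L) {
  local <- vapply(
    seq_len(p), function(j) cached_score(cache, j, amat_parents(amat, j)),
    numeric(1)
  )

  # phase 1: plain greedy ascent to a single-move local optimum
  repeat {
    move <- best_move_scan(amat, cache, bl, p, local, tol)
    if (is.null(move)) break
    upd <- apply_move(amat, cache, local, move)
    amat <- upd$amat
    local <- upd$local
  }
  best_amat <- amat
  best_score <- sum(local)

  # phase 2: tabu exploration -- keep taking the best non-tabu move even when
  # it worsens the score, remembering the best graph seen; recently applied
  # moves may not be undone for tabu_len steps, and the search stops after
  # max_stall consecutive moves without a new best
  tabu <- character()
  stall <- 0L
  while (stall < max_stall) {
    move <- best_move_scan(amat, cache, bl, p, local, -Inf, forbidden = tabu)
    if (is.null(move)) break
    upd <- apply_move(amat, cache, local, move)
    amat <- upd$amat
    local <- upd$local
    tabu <- c(tabu, inverse_move_key(move))
    if (length(tabu) > tabu_len) tabu <- tabu[-1]
    sc <- sum(local)
    if (sc > best_score + tol) {
      best_score <- sc
      best_amat <- amat
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }

  # re-polish from the best graph found so the result is a local optimum
  if (!identical(best_amat, amat)) {
    amat <- best_amat
    local <- vapply(
      seq_len(p), function(j) cached_score(cache, j, amat_parents(amat, j)),
      numeric(1)
    )
  }
  repeat {
    move <- best_move_scan(amat, cache, bl, p, local, tol)
    if (is.null(move)) break
    upd <- apply_move(amat, cache, local, move)
    amat <- upd$amat
    local <- upd$local
  }

  list(amat = amat, score = sum(local))
}

#' Exhaustively score every DAG over a few variables
#'
#' Enumerates all directed acyclic graphs over the data columns (at most 4
#' variables; 543 DAGs for 4 nodes), scores each with the same Gaussian BIC
#' as [hill_climb()], and returns the global optimum. Used as the
#' independent oracle for the greedy search.
#'
#' @inheritParams hill_climb
#' @return A `hen_dag` carrying the globally optimal graph, with an extra
#'   element `n_dags` (number of acyclic graphs enumerated).
#' @export
exhaustive_search <- function(data, blacklist = NULL) {
  x <- standardize_columns(data)
  nodes <- colnames(x)
  p <- length(nodes)
  if (p > 4) stop("exhaustive enumeration supported for at most 4 variables")
  n <- nrow(x)
  bl <- blacklist_matrix(blacklist, nodes)
  S <- mle_cov(x)

  # local score of every (node, parent set) pair: p * 2^(p-1) regressions
  others <- lapply(seq_len(p), function(j) setdiff(seq_len(p), j))
  parent_sets <- lapply(seq_len(p), function(j) {
    sets <- list()
    oth <- others[[j]]
    for (mask in 0:(2^(p - 1) - 1)) {
      sets[[mask + 1]] <- oth[bitwAnd(mask, 2^(seq_len(p - 1) - 1)) > 0]
    }
    sets
  })
  local_tab <- lapply(seq_len(p), function(j) {
    vapply(parent_sets[[j]], function(pa) score_cov(S, n, j, pa), numeric(1))
  })

  m <- p * (p - 1L)
  slots <- which(diag(p) == 0, arr.ind = TRUE) # edge slot -> (from, to)
  is_acyclic <- function(amat) {
    indeg <- colSums(amat)
    alive <- rep(TRUE, p)
    repeat {
      free <- which(alive & indeg == 0)
      if (!length(free)) break
      for (v in free) {
        alive[v] <- FALSE
        indeg[amat[v, ] & alive] <- indeg[amat[v, ] & alive] - 1L
      }
    }
    !any(alive)
  }

  best <- -Inf
  best_amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  n_dags <- 0L
  for (g in 0:(2^m - 1)) {
    bits <- bitwAnd(g, 2^(seq_len(m) - 1)) > 0
    amat <- matrix(FALSE, p, p)
    amat[slots[bits, , drop = FALSE]] <- TRUE
    if (any(amat & t(amat)) || any(amat & bl)) next
    if (!is_acyclic(amat)) next
    n_dags <- n_dags + 1L
    sc <- 0
    for (j in seq_len(p)) {
      pa <- which(amat[, j])
      oth <- others[[j]]
      mask <- sum(2^(match(pa, oth) - 1))
      sc <- sc + local_tab[[j]][mask + 1]
    }
    if (sc > best) {
      best <- sc
      best_amat <- amat
    }
  }
  dimnames(best_amat) <- list(nodes, nodes)
  out <- new_hen_dag(best_amat, nodes, best, n)
  out$n_dags <- n_dags
  out
}

#' Is a DAG a single-move local optimum of the BIC score?
#'
#' Checks that no single arc addition, deletion or reversal (respecting the
#' blacklist and acyclicity) improves the Gaussian BIC score of the graph on
#' the given data.
#'
#' @param dag A `hen_dag` (or `hen_network`).
#' @param data The data the graph is scored on.
#' @param blacklist Optional forbidden-arc table.
#' @param tol Minimum improvement counting as an improving move.
#' @return `TRUE` if no improving move exists.
#' @export
is_local_optimum <- function(dag, data, blacklist = NULL, tol = 1e-6) {
  x <- standardize_columns(data)
  nodes <- colnames(x)
  stopifnot(identical(sort(nodes), sort(dag$nodes)))
  amat <- dag$amat[nodes, nodes]
  p <- length(nodes)
  bl <- blacklist_matrix(blacklist, nodes)
  cache <- new_score_cache(mle_cov(x), nrow(x))
  local <- vapply(
    seq_len(p), function(j) cached_score(cache, j, amat_parents(amat, j)),
    numeric(1)
  )
  is.null(best_move_scan(amat, cache, bl, p, local, tol))
}

#' Structural Hamming distance between two skeletons
#'
#' Counts unordered node pairs adjacent in one graph but not the other
#' (edge directions ignored).
#'
#' @param arcs_a,arcs_b Data frames with columns `from`, `to` (or `hen_dag`
#'   / `hen_network` objects).
#' @return Integer edit distance between the two skeletons.
#' @export
shd_skeleton <- function(arcs_a, arcs_b) {
  as_pairs <- function(a) {
    if (inherits(a, c("hen_dag", "hen_network"))) a <- a$arcs
    a <- as.data.frame(a)
    if (!nrow(a)) {
      return(character())
    }
    unique(paste(pmin(a$from, a$to), pmax(a$from, a$to), sep = "~"))
  }
  pa <- as_pairs(arcs_a)
  pb <- as_pairs(arcs_b)
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}
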