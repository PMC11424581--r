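# Independent reference implementations used as oracles. These are written
# naively (row loops, recursion, explicit closures) on purpose: they share
# no code with the package internals they check.

# --- Boolean activation -----------------------------------------------------

# one-node inhibition-dominant update, truth-table style
.oracle_update <- function(edf, state, g, clamped) {
  if (g == clamped) return(1L)
  val <- NA_integer_
  for (i in seq_len(nrow(edf))) {
    if (edf$target[i] != g) next
    s <- state[[edf$source[i]]]
    if (!is.na(s) && s == 1L) {
      if (edf$sign[i] == -1) return(0L)
      val <- 1L
    }
  }
  val
}

# procedural re-statement of the simulation: recursive DFS preorder pass
# (lexicographic target order), then synchronous sweeps bounded by N
oracle_activation <- function(edf, tf) {
  nd <- sort(unique(c(edf$source, edf$target)))
  st <- stats::setNames(rep(NA_integer_, length(nd)), nd)
  st[tf] <- 1L
  visited <- stats::setNames(logical(length(nd)), nd)
  visited[tf] <- TRUE
  dfs <- function(v) {
    for (w in sort(unique(edf$target[edf$source == v]))) {
      if (!visited[[w]]) {
        visited[[w]] <<- TRUE
        st[w] <<- .oracle_update(edf, st, w, tf)
        dfs(w)
      }
    }
  }
  dfs(tf)
  converged <- FALSE
  for (i in seq_along(nd)) {
    new <- st
    for (g in nd) new[g] <- .oracle_update(edf, st, g, tf)
    if (identical(unname(new), unname(st))) {
      converged <- TRUE
      break
    }
    st <- new
  }
  if (!converged) {
    new <- st
    for (g in nd) new[g] <- .oracle_update(edf, st, g, tf)
    changed <- nd[!mapply(identical, as.list(new), as.list(st))]
    st[changed] <- NA_integer_
  }
  attr(st, "converged") <- converged
  st
}

# all fixed points of the clamped synchronous map, by 3^N enumeration
oracle_fixed_points <- function(edf, tf) {
  nd <- sort(unique(c(edf$source, edf$target)))
  vals <- list(NA_integer_, 0L, 1L)
  grids <- do.call(expand.grid, rep(list(1:3), length(nd)))
  out <- list()
  for (r in seq_len(nrow(grids))) {
    st <- stats::setNames(unlist(vals[as.integer(grids[r, ])]), nd)
    if (is.na(st[[tf]]) || st[[tf]] != 1L) next
    img <- st
    for (g in nd) img[g] <- .oracle_update(edf, st, g, tf)
    if (identical(unname(img), unname(st))) out[[length(out) + 1]] <- st
  }
  out
}

# --- Pruning ----------------------------------------------------------------

# spec-stated consistency of a kept-edge subset, evaluated literally
oracle_prune_consistent <- function(edf, keep, st) {
  for (g in unique(edf$target)) {
    rows <- which(edf$target == g & keep)
    up_inh <- any(edf$sign[rows] == -1 & st[edf$source[rows]] == 1L)
    up_act <- any(edf$sign[rows] == 1 & st[edf$source[rows]] == 1L)
    if (st[[g]] == 1L) {
      if (up_inh) return(FALSE)
      if (length(rows) > 0 && !up_act) return(FALSE)
    } else {
      if (!up_inh && up_act) return(FALSE)
    }
  }
  TRUE
}

# lexicographic optimum (explained genes, then edges) over all edge subsets
oracle_prune_best <- function(edf, st) {
  nE <- nrow(edf)
  best_key <- c(-1L, -1L)
  for (code in 0:(2^nE - 1)) {
    keep <- bitwAnd(code, 2^(seq_len(nE) - 1)) > 0
    if (!oracle_prune_consistent(edf, keep, st)) next
    key <- c(length(unique(edf$target[keep])), sum(keep))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2]))
      best_key <- key
  }
  best_key
}

# --- Hierarchy --------------------------------------------------------------

# Krackhardt hierarchy from a Warshall reachability closure
oracle_hierarchy <- function(edf) {
  nd <- sort(unique(c(edf$source, edf$target)))
  n <- length(nd)
  R <- matrix(FALSE, n, n, dimnames = list(nd, nd))
  for (i in seq_len(nrow(edf))) R[edf$source[i], edf$target[i]] <- TRUE
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (R[i, k] && R[k, j]) R[i, j] <- TRUE
  diag(R) <- FALSE
  sym <- 0L
  either <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (R[i, j] || R[j, i]) either <- either + 1L
    if (R[i, j] && R[j, i]) sym <- sym + 1L
  }
  if (either == 0L) return(NA_real_)
  1 - sym / either
}

# --- ORA --------------------------------------------------------------------

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper_tail <- function(overlap, set_size, n_background, n_query) {
  js <- overlap:min(set_size, n_query)
  sum(choose(set_size, js) *
        choose(n_background - set_size, n_query - js)) /
    choose(n_background, n_query)
}

# --- misc generators --------------------------------------------------------

random_signed_digraph <- function(n_nodes, p_edge = 0.4,
                                  self_loops = TRUE) {
  nd <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = nd, target = nd, stringsAsFactors = FALSE)
  if (!self_loops) pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  e$sign <- sample(c(-1, 1), nrow(e), replace = TRUE)
  rownames(e) <- NULL
  e
}

make_trn <- function(edf, states = NULL) {
  nd <- sort(unique(c(edf$source, edf$target)))
  if (is.null(states)) states <- stats::setNames(rep(1L, length(nd)), nd)
  TRN(edf, BooleanProfile(states))
}
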