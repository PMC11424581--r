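#' @include AllClasses.R
NULL

# in-edge index: for each node, integer rows of the edge table targeting it
.in_index <- function(e, nd) {
  idx <- split(seq_len(nrow(e)), factor(e$target, levels = nd))
  names(idx) <- nd
  idx
}

# one-node update under inhibition dominance; st uses NA = undetermined
.update_node <- function(st, e, rows) {
  if (!length(rows)) return(NA_integer_)
  src <- st[e$source[rows]]
  sgn <- e$sign[rows]
  if (any(!is.na(src) & src == 1L & sgn == -1)) return(0L)
  if (any(!is.na(src) & src == 1L & sgn == 1)) return(1L)
  NA_integer_
}

#' Boolean activation simulation of a transcription factor
#'
#' Every network element starts undetermined; the chosen TF is clamped
#' active and its consequences are propagated under inhibition-dominant
#' logic: a node is inhibited (0) if any determined regulator that inhibits
#' it is active, otherwise active (1) if any determined activator is
#' active, otherwise undetermined. Propagation runs depth-first from the
#' activated TF (out-edges in lexicographic target order), followed by
#' synchronous sweeps (at most N, the network size) until a fixed point.
#' If cyclic inhibition prevents convergence, the still-oscillating nodes
#' are forced undetermined and a warning is logged.
#'
#' @param trn A \linkS4class{TRN}.
#' @param tf a node of the network to activate.
#' @return Named integer vector over network nodes: 1 active, 0 inhibited,
#'   \code{NA} undetermined.
#' @examples
#' trn <- TRN(data.frame(source = "A", target = c("B", "C"),
#'                       sign = c(1, -1)),
#'            BooleanProfile(c(A = 1, B = 1, C = 0)))
#' simulateActivation(trn, "A")  # A=1, B=1, C=0
#' @export
simulateActivation <- function(trn, tf) {
  nd <- nodes(trn)
  if (!tf %in% nd) stop("TF '", tf, "' is not in the network")
  e <- edges(trn)
  inx <- .in_index(e, nd)
  st <- stats::setNames(rep(NA_integer_, length(nd)), nd)
  st[tf] <- 1L

  # depth-first pass from the activated TF, lexicographic target order
  out_nbrs <- lapply(stats::setNames(nd, nd),
                     function(v) sort(unique(e$target[e$source == v])))
  visited <- stats::setNames(logical(length(nd)), nd)
  visited[tf] <- TRUE
  stack <- rev(out_nbrs[[tf]])
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (visited[[v]]) next
    visited[[v]] <- TRUE
    if (v != tf) st[v] <- .update_node(st, e, inx[[v]])
    stack <- c(stack, rev(out_nbrs[[v]]))
  }

  # synchronous sweeps to a fixed point, bounded by N
  n_max <- length(nd)
  converged <- FALSE
  for (i in seq_len(n_max)) {
    new <- st
    for (v in nd)
      if (v != tf) new[v] <- .update_node(st, e, inx[[v]])
    if (identical(unname(new), unname(st))) {
      converged <- TRUE
      break
    }
    st <- new
  }
  if (!converged) {
    new <- st
    for (v in nd)
      if (v != tf) new[v] <- .update_node(st, e, inx[[v]])
    unstable <- nd[xor(is.na(new), is.na(st)) |
                     (!is.na(new) & !is.na(st) & new != st)]
    if (length(unstable)) {
      .log("warn", "activation of ", tf, " did not converge in ", n_max,
           " sweeps; forcing undetermined: ",
           paste(unstable, collapse = ", "))
      st[unstable] <- NA_integer_
    }
  }
  st
}

#' Master-regulator score of one transcription factor
#'
#' The score is the fraction of the network whose booleanized profile state
#' is reproduced by simulating the TF's activation: the number of nodes
#' whose simulated state is determined and matches the profile (the TF
#' itself included), divided by the network size N. A TF whose own profile
#' state is down-regulated scores 0 -- activating it cannot explain its own
#' state. An end node with profile state 1 explains only itself and scores
#' exactly 1/N; a TF atop a fully hierarchical, fully consistent network
#' scores 1.
#'
#' @param trn A \linkS4class{TRN}; its own profile is used.
#' @param tf node to score.
#' @return Numeric score in [0, 1].
#' @export
tfScore <- function(trn, tf) {
  st <- profileStates(trn)
  if (!tf %in% nodes(trn)) stop("TF '", tf, "' is not in the network")
  if (st[[tf]] == 0L) return(0)
  sim <- simulateActivation(trn, tf)
  matched <- sum(!is.na(sim) & sim == st[names(sim)])
  matched / networkSize(trn)
}

#' Score all regulators of a network
#'
#' Runs the activation simulation for every TF that appears as an edge
#' source and classifies master regulators: TFs whose activation determines
#' at least \code{mr_threshold} (default 30\%) of the network in agreement
#' with the profile.
#'
#' @param trn A \linkS4class{TRN}.
#' @param mr_threshold inclusive master-regulator score threshold.
#' @return data.frame with columns \code{tf}, \code{score},
#'   \code{determined} (matched node count), \code{n} (network size) and
#'   \code{is_mr}, sorted by decreasing score.
#' @export
scoreAllTFs <- function(trn, mr_threshold = 0.30) {
  tfs <- sort(unique(edges(trn)$source))
  n <- networkSize(trn)
  score <- vapply(tfs, function(tf) tfScore(trn, tf), numeric(1))
  out <- data.frame(tf = tfs, score = unname(score),
                    determined = as.integer(round(unname(score) * n)),
                    n = n, is_mr = unname(score) >= mr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Master regulators of a score table
#'
#' @param score_table output of [scoreAllTFs()].
#' @param mr_threshold inclusive score threshold, default 0.30.
#' @return Character vector of master-regulator TFs.
#' @export
classifyMasterRegulators <- function(score_table, mr_threshold = 0.30) {
  score_table$tf[score_table$score >= mr_threshold]
}

#' Aggregate TF scores across conditions
#'
#' Builds the TF x condition score matrix (a TF absent from a condition's
#' network scores 0 there), ranks TFs by mean score and returns the top
#' \code{k} together with the full matrix for external clustering or
#' heatmaps. A mean-rank column is also reported (ranks computed per
#' condition on the filled matrix, ties to the minimum) for users who
#' prefer rank aggregation.
#'
#' @param tables named list of [scoreAllTFs()] outputs, one per condition
#'   (cell type, study, ...).
#' @param k number of top TFs to report, default 30.
#' @return List with \code{ranking} (data.frame tf, mean_score, mean_rank,
#'   top k by mean score) and \code{matrix} (full TF x condition scores).
#' @export
aggregateTopTFs <- function(tables, k = 30) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables)))
    names(tables) <- paste0("condition", seq_along(tables))
  tfs <- sort(unique(unlist(lapply(tables, `[[`, "tf"))))
  mat <- matrix(0, length(tfs), length(tables),
                dimnames = list(tfs, names(tables)))
  for (cond in names(tables)) {
    t <- tables[[cond]]
    mat[t$tf, cond] <- t$score
  }
  mean_score <- rowMeans(mat)
  ranks <- apply(-mat, 2, rank, ties.method = "min")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = length(tables))
  mean_rank <- rowMeans(ranks)
  ord <- order(-mean_score, tfs)
  top <- utils::head(ord, k)
  list(ranking = data.frame(tf = tfs[top], mean_score = mean_score[top],
                            mean_rank = mean_rank[top],
                            row.names = NULL, stringsAsFactors = FALSE),
       matrix = mat)
}
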