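#' @include AllClasses.R
NULL

#' Filter a differential-expression table
#'
#' Retains genes whose expression change is material: the absolute average
#' log fold change exceeds \code{lfc_min}, or the gene is detected in more
#' than \code{pct_min} of the cells in both conditions.
#'
#' @param de data.frame with canonical DE columns (see [readDETable()]).
#' @param lfc_min minimum |avg_log_fc| (strict), default 0.25.
#' @param pct_min minimum detection fraction in both conditions (strict),
#'   default 0.10.
#' @return The filtered data.frame.
#' @examples
#' de <- data.frame(gene = c("a", "b", "c"),
#'                  avg_log_fc = c(0.30, 0.10, 0.10),
#'                  p_adj = 0.01,
#'                  pct_cond1 = c(0.05, 0.15, 0.15),
#'                  pct_cond2 = c(0.05, 0.12, 0.05))
#' filterDE(de)$gene  # "a" by fold change, "b" by detection
#' @export
filterDE <- function(de, lfc_min = 0.25, pct_min = 0.10) {
  keep <- abs(de$avg_log_fc) > lfc_min |
    (de$pct_cond1 > pct_min & de$pct_cond2 > pct_min)
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Booleanize differential expression
#'
#' Maps log fold changes to binary states: positive to 1 (up-regulated),
#' negative to 0 (down-regulated). A fold change of exactly zero defines
#' neither state, so the gene is excluded from the profile.
#'
#' @param de filtered DE data.frame.
#' @return A \linkS4class{BooleanProfile}.
#' @export
booleanize <- function(de) {
  de <- de[de$avg_log_fc != 0, , drop = FALSE]
  BooleanProfile(stats::setNames(as.integer(de$avg_log_fc > 0), de$gene))
}

# edge classes for one target given regulator states:
# up-inhibitor  = inhibiting edge whose source is up   (state 1)
# up-activator  = activating edge whose source is up
.edge_flags <- function(e, st) {
  src_up <- st[e$source] == 1L
  list(up_inh = e$sign == -1 & src_up, up_act = e$sign == 1 & src_up)
}

# consistency of an edge subset (logical `keep`) for one target state
.gene_consistent <- function(keep, flags, g_state) {
  if (g_state == 1L) {
    if (any(flags$up_inh & keep)) return(FALSE)
    !any(keep) || any(flags$up_act & keep)
  } else {
    any(flags$up_inh & keep) || !any(flags$up_act & keep)
  }
}

# closed-form maximum-cardinality consistent subset for one target
.prune_gene_rule <- function(flags, g_state) {
  n <- length(flags$up_inh)
  if (g_state == 1L) {
    if (any(flags$up_act)) !flags$up_inh else rep(FALSE, n)
  } else {
    if (any(flags$up_inh)) rep(TRUE, n) else !flags$up_act
  }
}

# exhaustive per-gene subset enumeration; lexicographic objective
# (explained gene first, then edge count)
.prune_gene_enum <- function(flags, g_state) {
  n <- length(flags$up_inh)
  best <- rep(FALSE, n)
  best_key <- c(0L, 0L)  # (explained, edges)
  for (code in seq_len(2^n) - 1L) {
    keep <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    if (!.gene_consistent(keep, flags, g_state)) next
    key <- c(as.integer(any(keep)), sum(keep))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- keep
      best_key <- key
    }
  }
  best
}

#' Prune a prior knowledge network against a Boolean profile
#'
#' Applies inhibition-dominant regulatory logic: one up-regulated inhibitor
#' suffices to explain the down-regulation of its target regardless of how
#' many activating edges point at it. Starting from the prior knowledge
#' network restricted to profile genes (and to regulators in
#' \code{tf_universe}), the maximum set of edges consistent with the profile
#' is retained: an up-regulated target may keep no up-regulated inhibitor
#' and, if it keeps any edge, must keep an up-regulated activator; a
#' down-regulated target keeps everything when an up-regulated inhibitor
#' covers it, and otherwise drops its up-regulated activators. Per-target
#' subproblems are independent and solved exactly (enumerated for targets
#' with at most 16 candidate edges, closed-form rule above that; the choice
#' is logged). Genes retaining no edge drop out of the network, whose size N
#' is the number of unique regulators plus targets of retained edges.
#'
#' @param pkn \linkS4class{EdgeList} prior knowledge network (deduplicated).
#' @param profile \linkS4class{BooleanProfile} of the contrast.
#' @param tf_universe character vector of known transcription factors;
#'   edges whose source is not in it are discarded. Defaults to all sources
#'   in \code{pkn}.
#' @return A \linkS4class{TRN}.
#' @examples
#' pkn <- EdgeList(c("A", "C"), c("B", "B"), c(1, -1))
#' prof <- BooleanProfile(c(A = 1, B = 0, C = 1))
#' edges(prunePKN(pkn, prof))  # both edges kept: the inhibitor dominates
#' @export
prunePKN <- function(pkn, profile, tf_universe = unique(edges(pkn)$source)) {
  st <- profileStates(profile)
  if (!length(st)) stop("empty Boolean profile")
  e <- edges(pkn)
  e <- e[e$source %in% names(st) & e$target %in% names(st) &
           e$source %in% tf_universe, , drop = FALSE]
  if (!nrow(e)) {
    .log("warn", "no PKN edge connects profile genes; empty TRN")
    return(TRN(e, profile))
  }
  kept <- logical(nrow(e))
  for (g in unique(e$target)) {
    idx <- which(e$target == g)
    flags <- .edge_flags(e[idx, , drop = FALSE], st)
    kept[idx] <- if (length(idx) <= 16L)
      .prune_gene_enum(flags, st[[g]])
    else {
      .log("debug", "closed-form pruning rule for target ", g,
           " (", length(idx), " candidate edges)")
      .prune_gene_rule(flags, st[[g]])
    }
  }
  TRN(e[kept, , drop = FALSE], profile)
}

.edge_frame <- function(x) {
  if (methods::is(x, "EdgeList") || methods::is(x, "TRN")) edges(x)
  else as.data.frame(x)
}

#' Krackhardt hierarchy of a directed network
#'
#' Measures how hierarchical reachability is: among unordered node pairs
#' connected in at least one direction, the fraction NOT mutually reachable.
#' A rooted out-tree scores 1 (pure hierarchy); a two-node cycle scores 0.
#'
#' @param x A \linkS4class{TRN}, \linkS4class{EdgeList} or edge data.frame.
#' @return Numeric scalar in [0, 1].
#' @examples
#' krackhardtHierarchy(data.frame(source = c("A", "B", "C"),
#'                                target = c("B", "C", "B"), sign = 1))
#' # 2/3: of three connected pairs only {B, C} is reciprocal
#' @export
krackhardtHierarchy <- function(x) {
  e <- .edge_frame(x)
  nd <- unique(c(e$source, e$target))
  if (length(nd) < 2L) stop("hierarchy needs at least 2 nodes")
  g <- igraph::graph_from_data_frame(e[c("source", "target")],
                                     vertices = nd)
  reach <- is.finite(igraph::distances(g, mode = "out"))
  diag(reach) <- FALSE
  either <- reach | t(reach)
  both <- reach & t(reach)
  n_either <- sum(either[upper.tri(either)])
  if (n_either == 0L) stop("no reachable node pair; hierarchy undefined")
  1 - sum(both[upper.tri(both)]) / n_either
}

#' Fraction of unexplained DE genes reachable by signal-dependent TFs
#'
#' Among differentially expressed genes that are absent from the pruned
#' network yet have at least one known regulator in the prior knowledge
#' network, the fraction whose regulators include a signal-dependent
#' transcription factor (whose activity responds to extracellular signals
#' rather than its own expression).
#'
#' @param de_genes character vector of differentially expressed genes.
#' @param trn the pruned \linkS4class{TRN}.
#' @param pkn the full prior knowledge \linkS4class{EdgeList}.
#' @param sd_tfs curated character vector of signal-dependent TFs.
#' @return Numeric fraction in [0, 1].
#' @export
signalDependentFraction <- function(de_genes, trn, pkn, sd_tfs) {
  e <- edges(pkn)
  regulated <- de_genes[de_genes %in% e$target]
  unexplained <- setdiff(regulated, nodes(trn))
  if (!length(unexplained))
    stop("no DE gene is both regulated in the PKN and absent from the TRN; ",
         "fraction undefined")
  covered <- vapply(unexplained, function(g)
    any(e$source[e$target == g] %in% sd_tfs), logical(1))
  mean(covered)
}
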