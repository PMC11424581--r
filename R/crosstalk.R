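#' @include AllClasses.R
NULL

#' Differentially active signaling intermediates
#'
#' Selects molecules that switch from inhibited to active under the
#' intervention: present in the treated table with an activity score above
#' \code{active} (0.70) and inhibited in the control, i.e. scoring below
#' \code{inhibited} (0.30) or missing there -- \code{NA} entries count as
#' inhibited. A molecule absent or \code{NA} in the treated condition is
#' never selected. Both tables must be non-empty (a condition without any
#' result invalidates the comparison as a whole).
#'
#' @param treated,control named numeric score vectors in [0, 1], possibly
#'   with \code{NA}s (see [readScoreTable()]).
#' @param active activation cutoff (strict), default 0.70.
#' @param inhibited inhibition cutoff (strict), default 0.30.
#' @return Sorted character vector of selected molecules.
#' @examples
#' differentialIntermediates(c(Mapk14 = 0.8, App = 0.5),
#'                           c(Mapk14 = 0.2, App = 0.1))  # "Mapk14"
#' @export
differentialIntermediates <- function(treated, control, active = 0.70,
                                      inhibited = 0.30) {
  if (!length(treated) || !length(control))
    stop("both conditions need a non-empty score table")
  mol <- names(treated)
  ctrl <- control[mol]  # molecules absent from control become NA
  sel <- !is.na(treated) & treated > active &
    (is.na(ctrl) | ctrl < inhibited)
  sort(mol[sel])
}

#' Crosstalk component between regulatory and signaling networks
#'
#' A crosstalk exists only when some transcription factor has outgoing
#' edges in both the regulatory network and the signaling network (a shared
#' sink node is not enough). When it does, both edge sets are concatenated
#' and the weakly connected components of the union graph computed: a
#' single component is returned whole; with several, only the component
#' containing the signaling intermediate is kept. Edge directions are
#' preserved in the output; only connectivity ignores them.
#'
#' @param trn_edges \linkS4class{EdgeList} (or \linkS4class{TRN}) of
#'   regulatory edges.
#' @param sig_edges \linkS4class{EdgeList} of signaling edges; must contain
#'   the intermediate.
#' @param intermediate signaling intermediate symbol.
#' @return A \linkS4class{CrosstalkComponent}; empty when the shared-TF
#'   gate fails or the intermediate lies in no component.
#' @export
sharedComponent <- function(trn_edges, sig_edges, intermediate) {
  te <- .edge_frame(trn_edges)
  se <- .edge_frame(sig_edges)
  if (!intermediate %in% unique(c(se$source, se$target)))
    stop("intermediate '", intermediate, "' absent from signaling edges")
  empty <- methods::new("CrosstalkComponent", intermediate = character(),
                        genes = character(),
                        edges = data.frame(source = character(),
                                           target = character(),
                                           sign = numeric()))
  shared_tf <- intersect(unique(te$source), unique(se$source))
  if (!length(shared_tf)) {
    .log("info", "no TF with outgoing edges in both networks; no crosstalk")
    return(empty)
  }
  uni <- unique(rbind(te[c("source", "target", "sign")],
                      se[c("source", "target", "sign")]))
  nd <- unique(c(uni$source, uni$target))
  g <- igraph::graph_from_data_frame(uni[c("source", "target")],
                                     vertices = nd)
  comp <- igraph::components(g, mode = "weak")
  memb <- comp$membership
  if (comp$no > 1L) {
    if (!intermediate %in% names(memb)) {
      .log("warn", "intermediate '", intermediate,
           "' lies in no union component; empty crosstalk")
      return(empty)
    }
    keep <- names(memb)[memb == memb[[intermediate]]]
  } else keep <- names(memb)
  sub <- uni[uni$source %in% keep & uni$target %in% keep, , drop = FALSE]
  rownames(sub) <- NULL
  methods::new("CrosstalkComponent", intermediate = intermediate,
               genes = sort(keep), edges = sub)
}

#' Overrepresentation analysis of gene sets
#'
#' Hypergeometric upper-tail test of the overlap between a query gene set
#' and each collection member, against a user-supplied background, with
#' Benjamini-Hochberg false-discovery-rate control. Gene sets are
#' intersected with the background before testing.
#'
#' @param query character vector of genes of interest (must be contained in
#'   the background).
#' @param background character vector of assayable genes.
#' @param gene_sets named list of character vectors (see [readGMT()]).
#' @param fdr BH-adjusted significance threshold, default 0.05.
#' @return data.frame with columns \code{set}, \code{overlap},
#'   \code{set_size}, \code{p}, \code{padj}, \code{enriched}, ordered by
#'   \code{p}.
#' @export
oraTest <- function(query, background, gene_sets, fdr = 0.05) {
  query <- unique(query)
  background <- unique(background)
  if (!length(query) || !length(background))
    stop("query and background must be non-empty")
  if (!all(query %in% background))
    stop("query genes outside the background: ",
         paste(utils::head(setdiff(query, background)), collapse = ", "))
  N <- length(background)
  q <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], background)
    k <- length(intersect(query, s))
    m <- length(s)
    p <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = m, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$padj < fdr
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
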