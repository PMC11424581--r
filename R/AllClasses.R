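#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame isEmpty
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.valid_sign <- function(s) is.numeric(s) && all(s %in% c(-1, 1))

# ---------------------------------------------------------------- CellMatrix

#' Single-cell count matrix with condition metadata
#'
#' A thin \linkS4class{SingleCellExperiment} subclass holding raw UMI counts
#' (genes x cells, sparse) and the per-cell metadata columns the pipeline
#' requires: \code{cell_type}, \code{condition} (one treated label plus one or
#' two control labels) and \code{replicate}.
#'
#' @slot .Data inherited from \linkS4class{SingleCellExperiment}; the
#'   \code{"counts"} assay must be non-negative and integral.
#' @seealso [readCellMatrix()], [simulateCounts()]
#' @export
setClass("CellMatrix", contains = "SingleCellExperiment")

setValidity("CellMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
    if (length(v) && (any(v < 0) || any(v != round(v))))
      msg <- c(msg, "counts must be non-negative integers")
  }
  need <- c("cell_type", "condition", "replicate")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing cell metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene symbols")
  if (length(msg)) msg else TRUE
})

#' Construct a CellMatrix
#'
#' @param counts genes x cells matrix (dense or \pkg{Matrix} sparse) of raw
#'   non-negative integer counts, with gene symbols as rownames and cell
#'   barcodes as colnames.
#' @param cell_meta data.frame keyed by barcode (rownames or a
#'   \code{barcode} column) with columns \code{cell_type}, \code{condition},
#'   \code{replicate} and optionally \code{sex}.
#' @return A \linkS4class{CellMatrix}.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'             dimnames = list(c("Jun", "Fos"), c("c1", "c2")))
#' meta <- data.frame(row.names = c("c1", "c2"),
#'                    cell_type = "Tcell", condition = c("treated", "control"),
#'                    replicate = 1L)
#' cm <- CellMatrix(m, meta)
#' @export
CellMatrix <- function(counts, cell_meta) {
  if (!is.null(cell_meta$barcode) && is.null(rownames(cell_meta)))
    rownames(cell_meta) <- cell_meta$barcode
  if (is.null(colnames(counts)))
    stop("counts must have cell barcodes as colnames")
  if (!all(colnames(counts) %in% rownames(cell_meta)))
    stop("cells absent from cell metadata: ",
         paste(utils::head(setdiff(colnames(counts), rownames(cell_meta))),
               collapse = ", "))
  cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta))
  methods::new("CellMatrix", sce)
}

# ------------------------------------------------------------------ EdgeList

#' Signed directed edge list
#'
#' Container for signed, directed regulator-to-target interactions, the
#' common currency of the prior knowledge network, pruned regulatory
#' networks, signaling edges and ligand-receptor scaffolds. Exact duplicate
#' rows are removed at construction.
#'
#' @slot edges data.frame with character columns \code{source}, \code{target}
#'   and numeric \code{sign} in \{+1, -1\}.
#' @seealso [readEdgeList()], [prunePKN()]
#' @export
setClass("EdgeList", representation(edges = "data.frame"))

setValidity("EdgeList", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("source", "target", "sign") %in% colnames(e)))
    msg <- c(msg, "edge table needs columns source, target, sign")
  else {
    if (!.valid_sign(e$sign)) msg <- c(msg, "sign must be +1 or -1")
    if (anyDuplicated(e[c("source", "target", "sign")]))
      msg <- c(msg, "duplicate (source, target, sign) rows")
    if (any(!nzchar(e$source)) || any(!nzchar(e$target)))
      msg <- c(msg, "empty node symbol")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EdgeList
#'
#' @param source,target character vectors of regulator and target symbols.
#' @param sign numeric vector of +1 (activation) / -1 (inhibition); defaults
#'   to all activating.
#' @return An \linkS4class{EdgeList}; exact duplicates are dropped.
#' @examples
#' EdgeList(c("Jun", "Jun", "Fos"), c("Mmp9", "Mmp9", "Ccl2"), c(1, 1, -1))
#' @export
EdgeList <- function(source = character(), target = character(),
                     sign = rep(1, length(source))) {
  e <- data.frame(source = as.character(source),
                  target = as.character(target),
                  sign = as.numeric(sign),
                  stringsAsFactors = FALSE)
  e <- unique(e)
  rownames(e) <- NULL
  methods::new("EdgeList", edges = e)
}

#' @describeIn EdgeList-class edge table accessor
#' @param x An EdgeList.
#' @export
setMethod("edges", "EdgeList", function(x) x@edges)

#' @describeIn EdgeList-class nodes = union of sources and targets
#' @export
setMethod("nodes", "EdgeList",
          function(x) sort(unique(c(x@edges$source, x@edges$target))))

#' @describeIn EdgeList-class number of edges
#' @export
setMethod("length", "EdgeList", function(x) nrow(x@edges))

setMethod("show", "EdgeList", function(object) {
  cat("EdgeList with", nrow(object@edges), "edges over",
      length(nodes(object)), "nodes\n")
  if (nrow(object@edges))
    print(utils::head(object@edges, 5))
})

# ------------------------------------------------------------ BooleanProfile

#' Booleanized differential-expression profile
#'
#' Gene-level binary states derived from differential expression: positive
#' log fold changes map to 1 (up-regulated), negative to 0 (down-regulated).
#' Genes with a fold change of exactly zero carry no state and are excluded.
#'
#' @slot state named integer vector with values in \{0, 1\}.
#' @seealso [booleanize()]
#' @export
setClass("BooleanProfile", representation(state = "integer"))

setValidity("BooleanProfile", function(object) {
  s <- object@state
  msg <- character()
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
      msg <- c(msg, "states must be uniquely named by gene symbol")
    if (!all(s %in% c(0L, 1L))) msg <- c(msg, "states must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BooleanProfile
#'
#' @param state named vector of 0/1 gene states.
#' @return A \linkS4class{BooleanProfile}.
#' @examples
#' BooleanProfile(c(Jun = 1, Mmp9 = 0))
#' @export
BooleanProfile <- function(state = integer()) {
  s <- stats::setNames(as.integer(state), names(state))
  methods::new("BooleanProfile", state = s)
}

#' @describeIn BooleanProfile-class named 0/1 state vector
#' @param x A BooleanProfile.
#' @export
setMethod("profileStates", "BooleanProfile", function(x) x@state)

#' @describeIn BooleanProfile-class number of genes with a state
#' @export
setMethod("length", "BooleanProfile", function(x) length(x@state))

setMethod("show", "BooleanProfile", function(object) {
  cat("BooleanProfile:", sum(object@state == 1L), "up /",
      sum(object@state == 0L), "down genes\n")
})

# --------------------------------------------------------------------- TRN

#' Profile-consistent transcriptional regulatory network
#'
#' The pruned subnetwork of a prior knowledge network that is consistent
#' with a booleanized differential-expression profile under
#' inhibition-dominant logic. Its size N (the unit of master-regulator
#' scoring) is the number of unique regulators plus targets of the retained
#' edges; profile genes that keep no edge are not part of the network.
#'
#' @slot edges retained edge table (source, target, sign).
#' @slot profile \linkS4class{BooleanProfile} restricted to network nodes.
#' @seealso [prunePKN()], [tfScore()], [krackhardtHierarchy()]
#' @export
setClass("TRN", representation(edges = "data.frame",
                               profile = "BooleanProfile"))

setValidity("TRN", function(object) {
  msg <- character()
  nd <- unique(c(object@edges$source, object@edges$target))
  if (nrow(object@edges) && !.valid_sign(object@edges$sign))
    msg <- c(msg, "sign must be +1 or -1")
  if (!all(nd %in% names(object@profile@state)))
    msg <- c(msg, "every network node needs a profile state")
  if (length(msg)) msg else TRUE
})

#' Construct a TRN from retained edges and a profile
#'
#' @param edges data.frame (source, target, sign) of retained edges.
#' @param profile \linkS4class{BooleanProfile} covering the edge nodes (it is
#'   restricted to them).
#' @return A \linkS4class{TRN}.
#' @export
TRN <- function(edges, profile) {
  edges <- unique(as.data.frame(edges)[c("source", "target", "sign")])
  rownames(edges) <- NULL
  nd <- unique(c(edges$source, edges$target))
  st <- profileStates(profile)
  methods::new("TRN", edges = edges,
               profile = BooleanProfile(st[names(st) %in% nd]))
}

#' @describeIn TRN-class retained edge table
#' @param x A TRN.
#' @export
setMethod("edges", "TRN", function(x) x@edges)

#' @describeIn TRN-class nodes of the retained network
#' @export
setMethod("nodes", "TRN",
          function(x) sort(unique(c(x@edges$source, x@edges$target))))

#' @describeIn TRN-class network size N (unique regulators + targets)
#' @export
setMethod("networkSize", "TRN", function(x) length(nodes(x)))

#' @describeIn TRN-class profile states over network nodes
#' @export
setMethod("profileStates", "TRN", function(x) x@profile@state)

setMethod("show", "TRN", function(object) {
  cat("TRN: N =", networkSize(object), "nodes,",
      nrow(object@edges), "edges,",
      length(unique(object@edges$source)), "regulators\n")
})

# ------------------------------------------------------------ PipelineConfig

#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline in one validated object. Defaults
#' are the study-wide settings: 3 MADs for cell QC, DE kept at |log FC| >
#' 0.25 or both-condition detection > 10\%, master-regulator call at a score
#' of at least 0.30, signaling activation/inhibition at 0.70/0.30,
#' cell-communication uniqueness above a 0.90 significance, clustering
#' fallback above 30 clusters, and an ORA FDR of 0.05.
#'
#' @slot nmads positive MAD multiplier for cell QC.
#' @slot de_lfc_min minimum |log fold change| for DE retention.
#' @slot de_pct_min minimum detection fraction (both conditions) for DE
#'   retention.
#' @slot mr_threshold master-regulator score threshold (inclusive).
#' @slot sig_active,sig_inhibited signaling intermediate activity cutoffs.
#' @slot cc_significance cell-communication significance cutoff (strict).
#' @slot max_clusters cluster count above which the fallback partition is
#'   used.
#' @slot ora_fdr BH-adjusted significance threshold for overrepresentation.
#' @slot seed integer seed for stochastic steps.
#' @slot passthrough free-form list of settings forwarded verbatim to
#'   upstream tools (e.g. hotspot cutoff 30, percentile 70); never
#'   interpreted here.
#' @seealso [readPipelineConfig()]
#' @export
setClass("PipelineConfig",
         representation(nmads = "numeric", de_lfc_min = "numeric",
                        de_pct_min = "numeric", mr_threshold = "numeric",
                        sig_active = "numeric", sig_inhibited = "numeric",
                        cc_significance = "numeric", max_clusters = "integer",
                        ora_fdr = "numeric", seed = "integer",
                        passthrough = "list"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@nmads <= 0) msg <- c(msg, "nmads must be > 0")
  if (!(object@sig_inhibited >= 0 && object@sig_inhibited < object@sig_active &&
        object@sig_active <= 1))
    msg <- c(msg, "need 0 <= sig_inhibited < sig_active <= 1")
  if (!(object@mr_threshold > 0 && object@mr_threshold <= 1))
    msg <- c(msg, "mr_threshold must be in (0, 1]")
  if (object@de_pct_min < 0 || object@de_pct_min > 1)
    msg <- c(msg, "de_pct_min must be a fraction")
  if (object@cc_significance < 0 || object@cc_significance > 1)
    msg <- c(msg, "cc_significance must be a fraction")
  if (object@max_clusters < 1L) msg <- c(msg, "max_clusters must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param nmads,de_lfc_min,de_pct_min,mr_threshold,sig_active,sig_inhibited,cc_significance,max_clusters,ora_fdr,seed,passthrough
#'   see \linkS4class{PipelineConfig}.
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' PipelineConfig(seed = 1L)
#' @export
PipelineConfig <- function(nmads = 3, de_lfc_min = 0.25, de_pct_min = 0.10,
                           mr_threshold = 0.30, sig_active = 0.70,
                           sig_inhibited = 0.30, cc_significance = 0.90,
                           max_clusters = 30L, ora_fdr = 0.05, seed = 1L,
                           passthrough = list()) {
  methods::new("PipelineConfig", nmads = nmads, de_lfc_min = de_lfc_min,
               de_pct_min = de_pct_min, mr_threshold = mr_threshold,
               sig_active = sig_active, sig_inhibited = sig_inhibited,
               cc_significance = cc_significance,
               max_clusters = as.integer(max_clusters), ora_fdr = ora_fdr,
               seed = as.integer(seed), passthrough = passthrough)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: nmads =", object@nmads,
      "| DE |lfc| >", object@de_lfc_min, "or pct >", object@de_pct_min,
      "\n  MR >=", object@mr_threshold,
      "| signaling", object@sig_active, "/", object@sig_inhibited,
      "| cell-comm >", object@cc_significance,
      "| max clusters", object@max_clusters,
      "| ORA FDR", object@ora_fdr, "\n")
})

# ------------------------------------------------------------ PlantedNetwork

#' Synthetic regulatory network with planted ground truth
#'
#' A rooted out-tree prior network whose root is the planted master
#' regulator, together with the Boolean profile produced by forward
#' simulation from the active root (optionally corrupted by state-flip
#' noise) and the fraction of node states the root's activation explains.
#'
#' @slot pkn \linkS4class{EdgeList} of the planted tree.
#' @slot profile \linkS4class{BooleanProfile} over all nodes.
#' @slot planted_mr root transcription factor symbol.
#' @slot explained_fraction fraction of nodes whose profile state matches the
#'   forward simulation of activating the root.
#' @seealso [simulatePlantedTRN()]
#' @export
setClass("PlantedNetwork",
         representation(pkn = "EdgeList", profile = "BooleanProfile",
                        planted_mr = "character",
                        explained_fraction = "numeric"))

setValidity("PlantedNetwork", function(object) {
  msg <- character()
  if (!object@planted_mr %in% object@pkn@edges$source)
    msg <- c(msg, "planted_mr must be a source in the planted network")
  if (object@explained_fraction < 0 || object@explained_fraction > 1)
    msg <- c(msg, "explained_fraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PlantedNetwork-class planted edge list
#' @param x A PlantedNetwork.
#' @export
setMethod("edges", "PlantedNetwork", function(x) x@pkn@edges)

#' @describeIn PlantedNetwork-class node symbols
#' @export
setMethod("nodes", "PlantedNetwork", function(x) nodes(x@pkn))

#' @describeIn PlantedNetwork-class profile states
#' @export
setMethod("profileStates", "PlantedNetwork", function(x) x@profile@state)

#' @describeIn PlantedNetwork-class root transcription factor
#' @export
setMethod("plantedMR", "PlantedNetwork", function(x) x@planted_mr)

#' @describeIn PlantedNetwork-class explained-state fraction
#' @export
setMethod("explainedFraction", "PlantedNetwork",
          function(x) x@explained_fraction)

setMethod("show", "PlantedNetwork", function(object) {
  cat("PlantedNetwork: root", object@planted_mr, "over",
      length(nodes(object@pkn)), "nodes;",
      sprintf("%.1f%%", 100 * object@explained_fraction),
      "of states explained\n")
})

# -------------------------------------------------------- CrosstalkComponent

#' Crosstalk component between a TRN and a signaling network
#'
#' The weakly connected component, containing a differentially active
#' signaling intermediate, of the union of regulatory and signaling edges --
#' extracted only when some transcription factor has outgoing edges in both
#' networks.
#'
#' @slot intermediate signaling intermediate symbol (empty when no crosstalk
#'   exists).
#' @slot genes node set of the component.
#' @slot edges directed signed edges of the component (directions preserved;
#'   connectivity was assessed ignoring direction).
#' @seealso [sharedComponent()]
#' @export
setClass("CrosstalkComponent",
         representation(intermediate = "character", genes = "character",
                        edges = "data.frame"))

#' @describeIn CrosstalkComponent-class component edges
#' @param x A CrosstalkComponent.
#' @export
setMethod("edges", "CrosstalkComponent", function(x) x@edges)

#' @describeIn CrosstalkComponent-class component gene set
#' @export
setMethod("nodes", "CrosstalkComponent", function(x) x@genes)

#' @describeIn CrosstalkComponent-class TRUE when no crosstalk was found
#' @export
setMethod("isEmpty", "CrosstalkComponent",
          function(x) length(x@genes) == 0L)

setMethod("show", "CrosstalkComponent", function(object) {
  if (length(object@genes) == 0L)
    cat("CrosstalkComponent: empty (no shared TF with outgoing edges in both networks)\n")
  else
    cat("CrosstalkComponent around", object@intermediate, ":",
        length(object@genes), "genes,", nrow(object@edges), "edges\n")
})
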