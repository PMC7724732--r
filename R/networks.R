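# Assembly of the SNP co-association, RNA co-abundance, shared and final
# networks with node annotations.

#' Construct a network object
#'
#' @param nodes data.frame with at least `id` and `type` ("gene" or
#'   "miRNA"); attribute columns `n_traits`, `top_trait`, `tf_class`,
#'   `in_shared` are filled with defaults when absent.
#' @param edges data.frame with `a`, `b` (node ids), `weight`,
#'   `provenance` ("snp", "rna", "mirna" or "shared"). Self-edges are
#'   rejected; each pair is stored once with `a < b`.
#' @return Object of class `spermnet_network`.
#' @export
new_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  nn <- nrow(nodes)
  if (!"type" %in% names(nodes)) nodes$type <- rep("gene", nn)
  if (!"n_traits" %in% names(nodes)) nodes$n_traits <- rep(0L, nn)
  if (!"top_trait" %in% names(nodes))
    nodes$top_trait <- rep(NA_character_, nn)
  if (!"tf_class" %in% names(nodes)) nodes$tf_class <- rep("none", nn)
  if (!"in_shared" %in% names(nodes)) nodes$in_shared <- rep(FALSE, nn)
  if (nrow(edges)) {
    if (any(edges$a == edges$b)) stop("self-edges not allowed")
    flip <- edges$a > edges$b
    tmp <- edges$a[flip]; edges$a[flip] <- edges$b[flip]
    edges$b[flip] <- tmp
    edges <- edges[!duplicated(edges[, c("a", "b")]), , drop = FALSE]
    missing_nodes <- setdiff(unique(c(edges$a, edges$b)), nodes$id)
    if (length(missing_nodes)) stop("edges reference unknown nodes")
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "spermnet_network")
}

#' @export
print.spermnet_network <- function(x, ...) {
  cat(sprintf("network: %d nodes (%d genes, %d miRNAs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "gene"),
              sum(x$nodes$type == "miRNA"), nrow(x$edges)))
  if (nrow(x$edges))
    cat("  provenance:",
        paste(sprintf("%s=%d", names(table(x$edges$provenance)),
                      table(x$edges$provenance)), collapse = ", "), "\n")
  invisible(x)
}

.network_from_pcit <- function(pc, provenance, type = "gene") {
  ed <- pcit_edges(pc, significant_only = TRUE)
  ids <- sort(unique(c(ed$a, ed$b)))
  new_network(
    nodes = data.frame(id = ids, type = type, stringsAsFactors = FALSE),
    edges = data.frame(a = ed$a, b = ed$b, weight = ed$r,
                       provenance = provenance, stringsAsFactors = FALSE)
  )
}

#' Build the SNP co-association network from an AWM
#'
#' Runs [pcit_filter()] over the AWM rows (features = genes, observations
#' = the trait columns); significant surviving edges form the SNP network.
#'
#' @param awm An `awm` (needs at least 3 trait columns).
#' @param p_max Correlation significance threshold.
#' @return A `spermnet_network` with provenance `"snp"`.
#' @export
build_snp_network <- function(awm, p_max = 0.05) {
  stopifnot(inherits(awm, "awm"))
  if (ncol(awm) < 3) stop("need at least 3 traits for PCIT trios")
  .network_from_pcit(pcit_filter(unclass(awm), p_max), "snp")
}

#' Build the RNA co-abundance network
#'
#' Runs [pcit_filter()] over the filtered log2 gene abundances (features =
#' genes, observations = samples).
#'
#' @param genes Log2-scale `abundance_matrix`.
#' @param p_max Correlation significance threshold.
#' @return A `spermnet_network` with provenance `"rna"`.
#' @export
build_rna_network <- function(genes, p_max = 0.05) {
  stopifnot(inherits(genes, "abundance_matrix"))
  if (!isTRUE(attr(genes, "log2")))
    stop("log2-stabilized abundances required")
  .network_from_pcit(pcit_filter(unclass(genes), p_max), "rna")
}

#' Intersect the SNP and RNA networks into the shared network
#'
#' Keeps the edges present in both networks (matched on the unordered gene
#' pair) and their incident nodes; `in_shared` is set on every node, and
#' edge provenance becomes `"shared"` (weight taken from the RNA network).
#' An empty intersection is a warning, not an error.
#'
#' @param snp_net,rna_net `spermnet_network` objects.
#' @return The shared `spermnet_network`.
#' @export
intersect_networks <- function(snp_net, rna_net) {
  stopifnot(inherits(snp_net, "spermnet_network"),
            inherits(rna_net, "spermnet_network"))
  key <- function(e) paste(e$a, e$b, sep = "|")
  common <- intersect(key(snp_net$edges), key(rna_net$edges))
  if (!length(common)) {
    warning("shared network is empty")
    return(new_network(
      nodes = data.frame(id = character(0), type = character(0)),
      edges = data.frame(a = character(0), b = character(0),
                         weight = numeric(0), provenance = character(0))
    ))
  }
  re <- rna_net$edges[key(rna_net$edges) %in% common, , drop = FALSE]
  re$provenance <- "shared"
  ids <- sort(unique(c(re$a, re$b)))
  nodes <- data.frame(id = ids, type = "gene", in_shared = TRUE,
                      stringsAsFactors = FALSE)
  new_network(nodes, re)
}

#' Build the final integrated network
#'
#' Starts from the shared network, adds every gene absent from it whose
#' abundance correlates with strictly more than `min_traits` phenotypes
#' together with that gene's RNA-network edges (and the partner nodes those
#' edges introduce), then adds the significant negative miRNA-gene edges
#' touching final-network genes. Node attributes are filled: `n_traits`
#' (significant trait correlations), `top_trait` (trait of maximum |r|,
#' ties broken lexicographically), `tf_class` (from the annotation), and
#' `in_shared`.
#'
#' @param shared Shared network from [intersect_networks()].
#' @param rna_net RNA network.
#' @param trait_corr `trait_correlations` for genes and miRNAs combined
#'   (rbind is fine).
#' @param mirna_edges data.frame from [mirna_gene_edges()] (may be empty).
#' @param tf_table Optional annotation with `gene_id`, `tf_class`.
#' @param min_traits Genes correlated with more than this many traits are
#'   pulled in (default 3, i.e. "> 3").
#' @return The final `spermnet_network`.
#' @export
build_final_network <- function(shared, rna_net, trait_corr,
                                mirna_edges = NULL, tf_table = NULL,
                                min_traits = 3) {
  stopifnot(inherits(shared, "spermnet_network"),
            inherits(rna_net, "spermnet_network"))
  sig <- trait_corr[trait_corr$significant, , drop = FALSE]
  cnt <- table(sig$feature)
  hub_genes <- names(cnt)[cnt > min_traits]
  hub_genes <- intersect(hub_genes, rna_net$nodes$id)
  add_genes <- setdiff(hub_genes, shared$nodes$id)

  edges <- shared$edges
  re <- rna_net$edges
  pulled <- re[re$a %in% add_genes | re$b %in% add_genes, , drop = FALSE]
  edges <- rbind(edges, pulled)
  node_ids <- unique(c(shared$nodes$id, add_genes,
                       pulled$a, pulled$b))

  if (!is.null(mirna_edges) && nrow(mirna_edges)) {
    me <- mirna_edges[mirna_edges$gene %in% node_ids, , drop = FALSE]
    if (nrow(me)) {
      edges <- rbind(edges, data.frame(
        a = me$gene, b = me$mirna, weight = me$r, provenance = "mirna",
        stringsAsFactors = FALSE
      ))
      node_ids <- unique(c(node_ids, me$mirna))
    }
  } else me <- NULL

  mir_ids <- if (!is.null(me)) unique(me$mirna) else character(0)
  nodes <- data.frame(
    id = node_ids,
    type = ifelse(node_ids %in% mir_ids, "miRNA", "gene"),
    in_shared = node_ids %in% shared$nodes$id,
    stringsAsFactors = FALSE
  )
  net <- new_network(nodes, edges)
  annotate_network(net, trait_corr, tf_table)
}

#' Fill node attributes from the correlation screen and TF annotation
#'
#' @param net A `spermnet_network`.
#' @param trait_corr `trait_correlations` covering the network's features.
#' @param tf_table Optional data.frame with `gene_id`, `tf_class`.
#' @return The network with `n_traits`, `top_trait`, `tf_class` filled.
#' @export
annotate_network <- function(net, trait_corr, tf_table = NULL) {
  sig <- trait_corr[trait_corr$significant, , drop = FALSE]
  nodes <- net$nodes
  for (i in seq_len(nrow(nodes))) {
    s <- sig[sig$feature == nodes$id[i], , drop = FALSE]
    nodes$n_traits[i] <- nrow(s)
    if (nrow(s)) {
      best <- which(abs(s$r) == max(abs(s$r)))
      nodes$top_trait[i] <- min(s$trait[best])
    }
  }
  if (!is.null(tf_table)) {
    j <- match(nodes$id, tf_table$gene_id)
    nodes$tf_class <- ifelse(is.na(j), "none", tf_table$tf_class[j])
  }
  net$nodes <- nodes
  net
}

#' Node/edge counts of each network stage
#'
#' @param ... Named `spermnet_network` objects.
#' @return data.frame: network, n_nodes, n_genes, n_mirnas, n_edges.
#' @export
network_summary <- function(...) {
  nets <- list(...)
  do.call(rbind, lapply(names(nets), function(nm) {
    x <- nets[[nm]]
    data.frame(network = nm, n_nodes = nrow(x$nodes),
               n_genes = sum(x$nodes$type == "gene"),
               n_mirnas = sum(x$nodes$type == "miRNA"),
               n_edges = nrow(x$edges), stringsAsFactors = FALSE)
  }))
}
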