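# Readers/writers for the external formats the pipeline touches: PLINK text
# ped/map, tab-delimited phenotype/abundance/annotation tables, and SIF /
# GraphML network exports. All tables are UTF-8, tab-delimited, with header
# rows; genomic coordinates are 1-based inclusive throughout.

#' Read PLINK text genotypes (.ped/.map)
#'
#' Alleles are recoded to counts of the `a1` allele (the minor allele as
#' observed in the file; ties broken alphabetically). A `"0 0"` genotype is
#' treated as missing.
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @return A `genotypes` object (see [simulate_genotypes()]); `freq` holds
#'   observed a1 frequencies.
#' @export
read_plink <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_raw <- read.table(map_path, header = FALSE, sep = "\t",
                        colClasses = "character")
  if (ncol(map_raw) != 4)
    stop("expected 4 columns in .map (chrom, snp_id, cM, bp)")
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  geno <- matrix(NA_integer_, n, m)
  ids <- character(n)
  a1 <- rep(NA_character_, m); a2 <- rep(NA_character_, m)
  allele_mat <- matrix(NA_character_, 2L * n, m)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop(sprintf("ragged .ped line %d: %d fields, expected %d",
                   i, length(f), 6 + 2 * m))
    ids[i] <- f[2]
    al <- f[-(1:6)]
    al[al == "0"] <- NA_character_
    allele_mat[2L * i - 1L, ] <- al[seq(1, 2 * m, by = 2)]
    allele_mat[2L * i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  freq <- numeric(m)
  for (j in seq_len(m)) {
    al <- allele_mat[, j]
    tab <- sort(table(al))
    us <- names(tab)
    if (length(us) == 0) { freq[j] <- NA_real_; next }
    if (length(us) == 1) { a1[j] <- us[1]; a2[j] <- us[1] }
    else {
      if (tab[[1]] == tab[[2]]) us <- sort(us)
      a1[j] <- us[1]; a2[j] <- us[2]
    }
    cnt <- (allele_mat[seq(1, 2 * n, 2), j] == a1[j]) +
      (allele_mat[seq(2, 2 * n, 2), j] == a1[j])
    geno[, j] <- as.integer(cnt)
    freq[j] <- mean(cnt, na.rm = TRUE) / 2
  }
  map <- data.frame(snp_id = map_raw[[2]], chrom = map_raw[[1]],
                    bp = as.integer(map_raw[[4]]), a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  rownames(geno) <- ids
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, map = map, freq = freq),
            class = "genotypes")
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param geno A `genotypes` object.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the ped path.
#' @export
write_plink <- function(geno, ped_path, map_path) {
  map <- geno$map
  write.table(
    data.frame(map$chrom, map$snp_id, 0L, map$bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  X <- geno$geno
  n <- nrow(X); m <- ncol(X)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- X[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, map$a1, map$a2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, map$a1, map$a2))
    pair <- character(2 * m)
    pair[seq(1, 2 * m, 2)] <- al1
    pair[seq(2, 2 * m, 2)] <- al2
    writeLines(paste(c("FAM", rownames(X)[i], "0", "0", "0", "-9", pair),
                     collapse = " "), con)
  }
  invisible(ped_path)
}

#' Write / read the phenotype table as TSV
#'
#' Columns: sample_id, farm, season_year, age, then the 25 traits.
#' @param traits A `trait_table`.
#' @param path File path.
#' @return `read_trait_table` returns a `trait_table`.
#' @export
write_trait_table <- function(traits, path) {
  write.table(as.data.frame(traits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (f in intersect(c("farm", "season_year", "age"), names(df)))
    df[[f]] <- factor(df[[f]])
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write / read an abundance matrix (features x samples) as TSV
#'
#' First column `feature_id`, remaining columns one per sample.
#' @param m An `abundance_matrix`.
#' @param path File path.
#' @param kind `"mRNA"` or `"miRNA"` (on read).
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  abundance_matrix(x, kind = kind)
}

#' Write / read the gene annotation table as TSV
#'
#' BED-like but 1-based inclusive: gene_id, chrom, start, end, biotype,
#' tf_class.
#' @param ann Annotation data.frame.
#' @param path File path.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

#' Export a network in SIF format
#'
#' One line per edge: `nodeA <relation> nodeB`, relation being the edge
#' provenance (snp / rna / mirna / shared).
#' @param net A `network` object (see [build_snp_network()]).
#' @param path Output path.
#' @export
write_network_sif <- function(net, path) {
  stopifnot(inherits(net, "spermnet_network"))
  if (nrow(net$edges) == 0) stop("refusing to write an empty network")
  writeLines(paste(net$edges$a, net$edges$provenance, net$edges$b),
             path)
  invisible(path)
}

#' Export a network in GraphML with node attributes
#'
#' Node attributes carried: `type`, `n_traits`, `top_trait`, `tf_class`,
#' `in_shared`; edge attributes: `weight` (correlation) and `provenance`.
#' Output is byte-stable for a fixed network.
#' @param net A `network` object.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "spermnet_network"))
  if (nrow(net$edges) == 0 && nrow(net$nodes) == 0)
    stop("refusing to write an empty network")
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a spermnet network to an igraph graph
#' @param net A `network` object.
#' @return An undirected igraph graph with node/edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "spermnet_network"))
  igraph::graph_from_data_frame(
    d = net$edges[, c("a", "b", "weight", "provenance")],
    directed = FALSE, vertices = net$nodes
  )
}

#' Write / read a network edge list as TSV
#'
#' Columns: a, b, weight, provenance; plus a companion node table.
#' @param net A `network` object.
#' @param edge_path,node_path Output paths.
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(edge_path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(edge_path, node_path) {
  edges <- read.table(edge_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  nodes <- read.table(node_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  new_network(nodes, edges)
}
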