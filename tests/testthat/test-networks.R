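# small helper: awm-like object from a plain matrix
as_awm <- function(M, key = "VIAB_5") {
  structure(scale(M), snp_ids = setNames(paste0("s", seq_len(nrow(M))),
                                         rownames(M)),
            key_trait = key, ap = 2,
            class = c("awm", "matrix", "array"))
}

test_that("SNP network edges stay within correlated gene blocks", {
  set.seed(41)
  # two orthogonal blocks: genes 1-3 share profile u, genes 4-6 share v
  u <- rnorm(12); v <- rnorm(12)
  v <- residuals(lm(v ~ u))   # exact orthogonality of the block profiles
  M <- rbind(
    gA1 = u + 0.1 * rnorm(12), gA2 = u + 0.1 * rnorm(12),
    gA3 = u + 0.1 * rnorm(12),
    gB1 = v + 0.1 * rnorm(12), gB2 = v + 0.1 * rnorm(12),
    gB3 = v + 0.1 * rnorm(12),
    # background genes so the column z-scoring leaves the block
    # profiles essentially untouched
    matrix(rnorm(30 * 12), 30, 12,
           dimnames = list(sprintf("gN%02d", 1:30), NULL))
  )
  colnames(M) <- sprintf("T%02d", 1:12)
  net <- build_snp_network(as_awm(M))
  expect_true(all(net$edges$provenance == "snp"))
  blockA <- c("gA1", "gA2", "gA3"); blockB <- c("gB1", "gB2", "gB3")
  cross <- (net$edges$a %in% blockA & net$edges$b %in% blockB) |
    (net$edges$a %in% blockB & net$edges$b %in% blockA)
  expect_false(any(cross))
  expect_gt(nrow(net$edges), 0)
})

test_that("permuting trait columns leaves the SNP network unchanged", {
  set.seed(42)
  M <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(sprintf("g%d", 1:8), sprintf("T%d", 1:10)))
  n1 <- build_snp_network(as_awm(M))
  n2 <- build_snp_network(as_awm(M[, sample(10)]))
  expect_equal(n1$edges[, c("a", "b")], n2$edges[, c("a", "b")])
})

test_that("build_snp_network requires at least 3 traits", {
  M <- matrix(rnorm(6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("T1", "T2")))
  expect_error(build_snp_network(as_awm(M)), "3 traits")
})

test_that("network intersection keeps exactly the common edges", {
  mk <- function(pairs, prov) {
    ids <- sort(unique(unlist(pairs)))
    new_network(
      data.frame(id = ids, type = "gene", stringsAsFactors = FALSE),
      data.frame(a = vapply(pairs, `[`, "", 1),
                 b = vapply(pairs, `[`, "", 2),
                 weight = 0.5, provenance = prov,
                 stringsAsFactors = FALSE)
    )
  }
  gid <- sprintf("g%02d", 1:30)
  set.seed(43)
  all_pairs <- t(combn(gid, 2))
  idx <- sample(nrow(all_pairs), 45)
  snp_pairs <- lapply(idx[1:20], function(i) all_pairs[i, ])
  rna_pairs <- lapply(c(idx[16:20], idx[21:45]),
                      function(i) all_pairs[i, ])
  # 5 pairs (idx 16:20) are common by construction
  snp_net <- mk(snp_pairs, "snp"); rna_net <- mk(rna_pairs, "rna")
  sh <- intersect_networks(snp_net, rna_net)
  expect_equal(nrow(sh$edges), 5)
  key <- function(e) paste(e$a, e$b)
  expect_true(all(key(sh$edges) %in% key(snp_net$edges)))
  expect_true(all(key(sh$edges) %in% key(rna_net$edges)))
  expect_true(all(sh$nodes$in_shared))

  # disjoint networks -> empty shared network with a warning
  d1 <- mk(list(c("x1", "x2")), "snp"); d2 <- mk(list(c("y1", "y2")),
                                                 "rna")
  expect_warning(sh0 <- intersect_networks(d1, d2), "empty")
  expect_equal(nrow(sh0$edges), 0)
})

test_that("final network applies the >3-trait rule and miRNA edges", {
  mk_corr <- function(feature, traits, r = 0.5) {
    data.frame(feature = feature, trait = traits, r = r,
               p = 0.01, n = 40, significant = TRUE,
               stringsAsFactors = FALSE)
  }
  tc <- rbind(
    mk_corr("gHub", c("MT_5", "HABN", "NABN", "VIAB_5")),      # 4 traits
    mk_corr("gThree", c("MT_5", "HABN", "NABN")),              # 3 traits
    mk_corr("gPartner", "MT_5"),
    mk_corr("mir1", "MT_5", r = -0.6)
  )
  class(tc) <- c("trait_correlations", "data.frame")
  rna <- new_network(
    data.frame(id = c("gHub", "gPartner", "gThree", "gOther"),
               type = "gene"),
    data.frame(a = c("gHub", "gThree"), b = c("gPartner", "gOther"),
               weight = 0.7, provenance = "rna")
  )
  shared <- new_network(
    data.frame(id = c("gS1", "gS2"), type = "gene", in_shared = TRUE),
    data.frame(a = "gS1", b = "gS2", weight = 0.8,
               provenance = "shared")
  )
  me <- data.frame(gene = c("gHub", "gThree"), mirna = "mir1",
                   r = -0.6, p = 0.01)
  fin <- build_final_network(shared, rna, tc, mirna_edges = me,
                             tf_table = data.frame(gene_id = "gHub",
                                                   tf_class = "TF"))
  # gHub (4 traits) pulled in with its RNA edge and partner
  expect_true(all(c("gHub", "gPartner") %in% fin$nodes$id))
  # gThree (exactly 3 traits, not in shared, unconnected to added genes)
  expect_false("gThree" %in% fin$nodes$id)
  # shared network contained in final
  expect_true(all(shared$nodes$id %in% fin$nodes$id))
  expect_true(all(paste(shared$edges$a, shared$edges$b) %in%
                    paste(fin$edges$a, fin$edges$b)))
  # miRNA attached only through genes already in the final network
  expect_true("mir1" %in% fin$nodes$id)
  expect_equal(fin$nodes$type[fin$nodes$id == "mir1"], "miRNA")
  mir_edges <- fin$edges[fin$edges$provenance == "mirna", ]
  expect_equal(sort(unique(c(mir_edges$a, mir_edges$b))),
               c("gHub", "mir1"))
  # every miRNA node has an incident mirna-provenance edge
  for (mid in fin$nodes$id[fin$nodes$type == "miRNA"])
    expect_true(any(mir_edges$a == mid | mir_edges$b == mid))
  # node attributes filled from the correlation screen
  expect_equal(fin$nodes$n_traits[fin$nodes$id == "gHub"], 4L)
  expect_equal(fin$nodes$top_trait[fin$nodes$id == "gHub"], "HABN")
  expect_equal(fin$nodes$tf_class[fin$nodes$id == "gHub"], "TF")
  expect_true(fin$nodes$in_shared[fin$nodes$id == "gS1"])
  expect_false(fin$nodes$in_shared[fin$nodes$id == "gHub"])
})

test_that("self-edges and unknown nodes are rejected", {
  expect_error(new_network(data.frame(id = "a"),
                           data.frame(a = "a", b = "a", weight = 1,
                                      provenance = "rna")),
               "self-edges")
  expect_error(new_network(data.frame(id = "a"),
                           data.frame(a = "a", b = "zz", weight = 1,
                                      provenance = "rna")),
               "unknown")
})
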