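test_that("the ATC tree is the prefix closure with upward gene propagation", {
  tree <- build_atc_tree(tibble::tibble(gene_id = "GENE1",
                                        atc_code = "C07AB07"))
  expect_equal(tree$code, c("C", "C07", "C07A", "C07AB", "C07AB07"))
  expect_equal(tree$level, 1:5)
  expect_true(all(vapply(tree$gene_set, identical, logical(1), "GENE1")))
  expect_equal(tree$parent, c(NA, "C", "C07", "C07A", "C07AB"))

  sibs <- build_atc_tree(tibble::tibble(
    gene_id = c("G1", "G2"), atc_code = c("C07AB07", "C07AB12")))
  parent <- sibs$gene_set[[match("C07AB", sibs$code)]]
  expect_setequal(parent, c("G1", "G2"))

  empty <- build_atc_tree(tibble::tibble(gene_id = character(),
                                         atc_code = character()))
  expect_equal(nrow(empty), 0)

  expect_error(build_atc_tree(tibble::tibble(gene_id = "G", atc_code = "c7")),
               "malformed ATC code 'c7' at mapping row 1")
})

test_that("every node's gene set is the union over its subtree", {
  withr::with_seed(22, {
    codes <- c("A01AB02", "A01AB03", "A02BC01", "C07AB07", "C07AA05",
               "C10AA01", "N02BA01")
    mapping <- tibble::tibble(
      gene_id = sample(paste0("G", 1:10), 25, replace = TRUE),
      atc_code = sample(codes, 25, replace = TRUE))
    tree <- build_atc_tree(mapping)
    for (i in seq_len(nrow(tree))) {
      children <- which(!is.na(tree$parent) & tree$parent == tree$code[i])
      direct <- unique(mapping$gene_id[mapping$atc_code == tree$code[i]])
      expected <- sort(unique(c(direct, unlist(tree$gene_set[children]))))
      expect_equal(tree$gene_set[[i]], expected)
    }
  })
})

test_that("Fisher enrichment matches hand-computed and brute-force tails", {
  # one associated gene, one in-class: P(X >= 1) drawing 1 from {1 in, 1 out}
  got <- fisher_enrichment("G1", "G1", c("G1", "G2"))
  expect_equal(got$p, 0.5)
  expect_equal(c(got$a, got$b, got$c, got$d), c(1, 0, 0, 1))

  # no overlap cannot be enriched
  none <- fisher_enrichment("G1", "G2", c("G1", "G2", "G3"))
  expect_equal(none$p, 1)

  # large table against the enumeration oracle
  assoc <- paste0("A", 1:100)
  class_genes <- c(paste0("A", 1:10), paste0("C", 1:5))
  universe <- c(assoc, paste0("C", 1:5), paste0("U", 1:895))
  got <- fisher_enrichment(assoc, class_genes, universe)
  expect_equal(c(got$a, got$b, got$c, got$d), c(10, 90, 5, 895))
  expect_equal(got$p, oracle_hyper_tail(10, 90, 5, 895), tolerance = 1e-12)

  expect_error(fisher_enrichment("G1", "G1", character()), "empty")
  expect_error(fisher_enrichment("ZZ", "G1", "G1"), "subset")
})

test_that("one-sided p agrees with the hypergeometric oracle across tables", {
  withr::with_seed(23, {
    for (rep in 1:40) {
      a <- sample(0:12, 1); b <- sample(0:15, 1)
      c <- sample(0:12, 1); d <- sample(0:20, 1)
      if (a + b + c + d == 0) next
      genes <- paste0("g", seq_len(a + b + c + d))
      assoc <- genes[seq_len(a + b)]
      class_genes <- c(genes[seq_len(a)], genes[a + b + seq_len(c)])
      got <- fisher_enrichment(assoc, class_genes, genes)
      expect_equal(got$p, oracle_hyper_tail(a, b, c, d), tolerance = 1e-12)
    }
  })
})

test_that("enlarging the overlap never increases the one-sided p", {
  p_at <- function(a) {
    genes <- paste0("g", 1:40)
    fisher_enrichment(genes[1:10], c(genes[seq_len(a)], genes[11:15]),
                      genes)$p
  }
  ps <- vapply(1:9, p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("subtree minimum p propagates to ancestors", {
  tree <- build_atc_tree(tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    atc_code = c("C07AB07", "C07AA05", "C10AA01")))
  res <- atc_enrichment(tree, associated = c("G1"),
                        universe = paste0("G", 1:50))
  expect_true(all(res$min_p_subtree <= res$p + 1e-15))
  # a leaf is its own minimum
  leaf <- res[res$code == "C07AB07", ]
  expect_equal(leaf$min_p_subtree, leaf$p)
  # the root aggregates the best descendant
  root <- res[res$code == "C", ]
  expect_equal(root$min_p_subtree,
               min(res$min_p_subtree[startsWith(res$code, "C")]))
  # explicit parent/child example
  toy <- tibble::tibble(code = c("C", "C07"), level = 1:2,
                        parent = c(NA, "C"), p = c(0.5, 0.01))
  expect_equal(subtree_min_p(toy)$min_p_subtree, c(0.01, 0.01))
})

test_that("the ontology adapter honours the five-gene gate", {
  res <- tibble::tibble(gene_id = paste0("G", 1:10),
                        q = c(rep(0.01, 4), rep(0.5, 6)))
  expect_message(out <- ontology_gene_list(res), "needs more than 5")
  expect_null(out)

  res$q <- c(rep(0.01, 6), rep(0.5, 4))
  expect_equal(ontology_gene_list(res), paste0("G", 1:6))
})

test_that("enrichment results serialize to a nested JSON tree", {
  tree <- build_atc_tree(tibble::tibble(
    gene_id = c("G1", "G2"), atc_code = c("C07AB07", "C10AA01")))
  res <- atc_enrichment(tree, "G1", paste0("G", 1:20))
  path <- tempfile(fileext = ".json")
  write_atc_json(res, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed[[1]]$code, "C")
  expect_length(parsed[[1]]$children, 2)  # C07 and C10
})
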