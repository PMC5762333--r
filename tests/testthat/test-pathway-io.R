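# KGML parsing, regulation/expression/clinical readers, and the subpathway
# definition format.

kgml_file <- function(body, pathway = 'name="path:test" title="toy" org="hsa"') {
  path <- tempfile(fileext = ".xml")
  writeLines(c('<?xml version="1.0"?>', sprintf("<pathway %s>", pathway),
               body, "</pathway>"), path)
  path
}

test_that("KGML gene relations become single undirected edges", {
  path <- kgml_file(c(
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>'))
  g <- read_kgml(path)
  expect_setequal(g$nodes, c("hsa:1", "hsa:2"))
  expect_equal(nrow(g$edges), 1L)

  # symmetric relations collapse to one edge
  path2 <- kgml_file(c(
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '<relation entry1="2" entry2="1" type="PPrel"/>'))
  expect_equal(read_kgml(path2)$edges, g$edges)
})

test_that("multi-gene entries expand so each member inherits the relation", {
  path <- kgml_file(c(
    '<entry id="1" type="gene" name="hsa:1 hsa:2"/>',
    '<entry id="2" type="gene" name="hsa:3"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>'))
  g <- read_kgml(path)
  expect_setequal(g$nodes, c("hsa:1", "hsa:2", "hsa:3"))
  expect_equal(g$edges,
               canonical_edges(rbind(c("hsa:1", "hsa:3"), c("hsa:2", "hsa:3"))))
})

test_that("group entries are flattened to a clique and map entries dropped", {
  path <- kgml_file(c(
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<entry id="3" type="map" name="path:hsa00000"/>',
    '<entry id="4" type="group" name="undefined">',
    '  <component id="1"/><component id="2"/>',
    '</entry>'))
  g <- read_kgml(path)
  expect_setequal(g$nodes, c("hsa:1", "hsa:2"))
  expect_false(any(grepl("path:", g$nodes)))
  expect_equal(nrow(g$edges), 1L)  # the group clique
})

test_that("compound bridging joins gene entries sharing a compound", {
  body <- c(
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<entry id="3" type="compound" name="cpd:C00001"/>',
    '<relation entry1="1" entry2="3" type="ECrel"/>',
    '<relation entry1="3" entry2="2" type="ECrel"/>')
  g_off <- read_kgml(kgml_file(body))
  expect_equal(nrow(g_off$edges), 0L)
  g_on <- read_kgml(kgml_file(body), bridge_compounds = TRUE)
  expect_equal(nrow(g_on$edges), 1L)
  expect_setequal(c(g_on$edges), c("hsa:1", "hsa:2"))
})

test_that("KGML parse is deterministic under entry reordering", {
  a <- kgml_file(c(
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<entry id="3" type="gene" name="hsa:3"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>',
    '<relation entry1="2" entry2="3" type="PPrel"/>'))
  b <- kgml_file(c(
    '<entry id="3" type="gene" name="hsa:3"/>',
    '<entry id="1" type="gene" name="hsa:1"/>',
    '<entry id="2" type="gene" name="hsa:2"/>',
    '<relation entry1="2" entry2="3" type="PPrel"/>',
    '<relation entry1="1" entry2="2" type="PPrel"/>'))
  ga <- read_kgml(a); gb <- read_kgml(b)
  expect_identical(ga$nodes, gb$nodes)
  expect_identical(ga$edges, gb$edges)
})

test_that("malformed XML and gene-free files are handled as specified", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<pathway><entry", bad)
  expect_error(read_kgml(bad), basename(bad), fixed = TRUE)

  empty <- kgml_file('<entry id="1" type="map" name="path:x"/>')
  expect_warning(g <- read_kgml(empty), "no gene entries")
  expect_length(g$nodes, 0)
  expect_equal(nrow(g$edges), 0L)
})

test_that("parsed graphs satisfy the type invariants", {
  set.seed(42)
  for (i in 1:10) {
    pg <- random_pathway_graph(sample(3:8, 1), runif(1, 0.2, 0.9))
    expect_silent(validate_pathway_graph(pg))
    if (nrow(pg$edges)) {
      expect_true(all(c(pg$edges) %in% pg$nodes))
      expect_true(all(pg$edges[, 1] < pg$edges[, 2]))  # canonical, no loops
    }
  }
})

test_that("regulation reader deduplicates, skips headers, rejects bad rows", {
  f <- tempfile()
  writeLines(c("L1\tg1", "L2\tg2", "L1\tg1"), f)
  tab <- suppressMessages(read_regulations(f))
  expect_equal(nrow(tab), 2L)

  writeLines(c("lncRNA\tgene", "L1\tg1"), f)
  tab <- suppressMessages(read_regulations(f))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$lncrna, "L1")

  writeLines(character(0), f)
  expect_warning(tab <- read_regulations(f), "empty")
  expect_equal(nrow(tab), 0L)

  writeLines(c("L1\tg1", "L2"), f)
  expect_error(read_regulations(f), "line 2")

  expect_error(regulation_table(c("x", "L1"), c("g1", "x")), "both")
})

test_that("expression matrices round-trip and invalid values are rejected", {
  m <- matrix(c(0, 1.5, 2.25, 3, 0.001, 7), nrow = 3,
              dimnames = list(c("hsa:1", "hsa:2", "lnc:1"), c("s1", "s2")))
  f <- tempfile()
  write_expression(m, f)
  expect_equal(read_expression(f), m)

  writeLines(c("id\ts1", "a\t1", "a\t2"), f)
  expect_error(read_expression(f), "duplicate feature.*a")
  writeLines(c("id\ts1", "a\t-1"), f)
  expect_error(read_expression(f), "negative.*'a'")
  writeLines(c("id\ts1", "a\tNA"), f)
  expect_error(read_expression(f), "missing")
})

test_that("clinical reader validates times, events and ids", {
  f <- tempfile()
  writeLines(c("sample_id\ttime\tevent", "s1\t10\t1", "s2\t5\t0"), f)
  cl <- read_clinical(f)
  expect_equal(cl$time, c(10, 5))

  writeLines(c("sample_id\ttime\tevent", "s1\t0\t1"), f)
  expect_error(read_clinical(f), "non-positive.*s1")
  writeLines(c("sample_id\ttime\tevent", "s1\t1\t2"), f)
  expect_error(read_clinical(f), "event.*s1")
  writeLines(c("sample_id\ttime\tevent", "s1\t1\t1", "s1\t2\t0"), f)
  expect_error(read_clinical(f), "duplicate")
  # round trip
  cl <- data.frame(sample_id = c("a", "b"), time = c(3.5, 9), event = c(1, 0))
  write_clinical(cl, f)
  expect_equal(read_clinical(f), cl)
})

test_that("subpathway definition files round-trip bit-exactly", {
  sp1 <- subpathway_graph("path:1_1", "path:1", "toy one",
                          genes = c("hsa:2", "hsa:1", "hsa:3"),
                          lncrnas = c("lnc:B", "lnc:A"),
                          gene_edges = rbind(c("hsa:1", "hsa:2"),
                                             c("hsa:3", "hsa:2")),
                          reg_edges = rbind(c("lnc:A", "hsa:1"),
                                            c("lnc:B", "hsa:3"),
                                            c("lnc:A", "hsa:2")))
  sp2 <- subpathway_graph("path:1_whole", "path:1", "toy one",
                          genes = c("hsa:1", "hsa:2"), lncrnas = character(0),
                          gene_edges = NULL,
                          reg_edges = NULL)
  f <- tempfile()
  write_subpathways(list(sp1, sp2), f)
  back <- read_subpathways(f)
  expect_equal(back, list(sp1, sp2))
  f2 <- tempfile()
  write_subpathways(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
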