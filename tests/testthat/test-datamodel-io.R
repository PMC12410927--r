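test_that("CSV round-trip preserves shape, names, and values", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "expr.csv")
  writeLines(c("cell,g1,g2", "c1,0,1.5", "c2,2.25,0", "c3,3,4.125"), path)
  m <- read_expression(path)
  expect_s3_class(m, "mixtraj_expr")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$cell_ids, c("c1", "c2", "c3"))
  expect_equal(m$gene_ids, c("g1", "g2"))
  expect_false(m$normalized)

  out <- file.path(dir, "roundtrip.csv")
  write_expression(m, out)
  m2 <- read_expression(out)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
})

test_that("MTX with sidecars and h5ad agree with the CSV reader on identical content", {
  dir <- withr::local_tempdir()
  vals <- matrix(c(0, 1.5, 2.25, 0, 3, 4.125), 3, 2,
                 dimnames = list(c("c1", "c2", "c3"), c("g1", "g2")))
  csv <- file.path(dir, "expr.csv")
  write_expression(expression_matrix(vals), csv)

  mtx <- file.path(dir, "expr.mtx")
  Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), mtx)
  writeLines(rownames(vals), file.path(dir, "expr.rows"))
  writeLines(colnames(vals), file.path(dir, "expr.cols"))

  m_csv <- read_expression(csv)
  m_mtx <- read_expression(mtx)
  expect_equal(m_mtx$values, m_csv$values)
  expect_equal(m_mtx$cell_ids, m_csv$cell_ids)

  # h5ad path shells out to python/anndata; build the fixture the same way
  h5 <- file.path(dir, "expr.h5ad")
  code <- paste("import sys, anndata, pandas as pd",
                "df = pd.read_csv(sys.argv[1], index_col=0)",
                "anndata.AnnData(df).write_h5ad(sys.argv[2])", sep = "; ")
  status <- suppressWarnings(system2("python", c("-c", shQuote(code), shQuote(csv), shQuote(h5)),
                                     stdout = FALSE, stderr = FALSE))
  expect_identical(status, 0L)
  m_h5 <- read_expression(h5)
  expect_equal(m_h5$values, m_csv$values, tolerance = 1e-9)
})

test_that("validation rejects negative and missing entries, naming the offender", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "neg.csv")
  writeLines(c("cell,g1,g2", "c1,0.5,1", "c2,-1.0,2"), path)
  expect_error(read_expression(path), "negative.*c2.*g1")
  expect_error(expression_matrix(matrix(c(1, NA), 1, 2)), "missing|non-finite")
  expect_error(read_expression(file.path(dir, "absent.csv")), "no such file")
})

test_that("transpose flag flips genes-as-rows files into the canonical layout", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "byrow.csv")
  writeLines(c("gene,c1,c2,c3", "g1,0,2.25,3", "g2,1.5,0,4.125"), path)
  m <- read_expression(path, transpose = TRUE)
  expect_equal(m$cell_ids, c("c1", "c2", "c3"))
  expect_equal(m$gene_ids, c("g1", "g2"))
  expect_equal(unname(m$values["c2", "g1"]), 2.25)
})

test_that("normalization is log1p then gene-wise min-max, with constant-gene and idempotence guards", {
  vals <- cbind(g1 = c(0, exp(1) - 1, exp(2) - 1), g2 = c(5, 5, 5))
  rownames(vals) <- paste0("c", 1:3)
  m <- expression_matrix(vals)
  expect_warning(norm <- normalize_expression(m), "constant")
  expect_equal(unname(norm$values[, "g1"]), c(0, 0.5, 1))
  expect_equal(unname(norm$values[, "g2"]), c(0, 0, 0))
  expect_true(norm$normalized)
  expect_false(m$normalized)      # original untouched
  expect_error(normalize_expression(norm), "already normalized")
})

test_that("normalization pins every non-constant gene to [0,1] regardless of affine rescaling", {
  set.seed(7)
  base <- matrix(rexp(60, 1), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (rep in 1:5) {
    a <- runif(1, 0.5, 4); b <- runif(1, 0, 2)
    m <- expression_matrix(a * base + b)
    n <- normalize_expression(m)
    expect_equal(unname(apply(n$values, 2, min)), rep(0, 3))
    expect_equal(unname(apply(n$values, 2, max)), rep(1, 3))
  }
})

test_that("marker panel parsing validates genes, branches, and multi-branch markers", {
  dir <- withr::local_tempdir()
  vals <- matrix(runif(12), 4, 3, dimnames = list(paste0("c", 1:4), c("g1", "g2", "g3")))
  m <- expression_matrix(vals)

  yml <- file.path(dir, "panel.yaml")
  writeLines(c("branches: [A, B]", "markers:", "  g1: A", "  g2: B"), yml)
  p <- suppressWarnings(parse_marker_panel(yml, m))
  expect_equal(p$K, 2L)
  expect_equal(p$marker_map$g1, 1L)
  expect_equal(p$marker_map$g2, 2L)

  # a gene marking two of three branches is switch-like in both, transient in the third
  yml3 <- file.path(dir, "panel3.yaml")
  writeLines(c("branches: [A, B, C]", "markers:", "  g1: [A, B]", "  g2: B", "  g3: C"), yml3)
  p3 <- suppressWarnings(parse_marker_panel(yml3, m))
  expect_equal(p3$marker_map$g1, c(1L, 2L))
  M <- mixtraj:::.marker_matrix(p3, m$gene_ids)
  expect_equal(unname(M["g1", ]), c(1L, 1L, 0L))

  bad <- file.path(dir, "bad.yaml")
  writeLines(c("branches: [A]", "markers:", "  gX: A"), bad)
  expect_error(suppressWarnings(parse_marker_panel(bad, m)), "gX")

  json <- file.path(dir, "panel.json")
  writeLines('{"branches": ["A", "B"], "markers": {"g1": "A", "g2": ["B"]}}', json)
  pj <- suppressWarnings(parse_marker_panel(json, m))
  expect_equal(pj$marker_map, p$marker_map)
})

test_that("panels enforce at least one marker per branch and warn under four", {
  expect_error(marker_panel(c("A", "B"), list(g1 = "A")), "no marker genes")
  expect_warning(marker_panel(c("A"), list(g1 = 1, g2 = 1)), "fewer than 4")
  big <- marker_panel("A", as.list(setNames(rep(1, 4), paste0("g", 1:4))))
  expect_equal(big$K, 1L)
})

test_that("duplicate gene ids error and duplicate cell ids are suffixed with a warning", {
  vals <- matrix(1:4, 2, 2)
  expect_error(expression_matrix(vals, c("c1", "c2"), c("g", "g")), "duplicate gene")
  expect_warning(m <- expression_matrix(vals, c("c", "c"), c("g1", "g2")), "duplicate cell")
  expect_equal(m$cell_ids, c("c", "c.1"))
})

test_that("priors files parse with per-gene overrides and reject bad hyperparameters", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "priors.yaml")
  writeLines(c("tau: [5, 2]",
               "genes:",
               "  g7:",
               "    tau: [-10, 1]"), yml)
  pr <- read_prior_spec(yml)
  expect_equal(pr$tau, c(5, 2))
  h <- mixtraj:::.expand_priors(pr, c("g1", "g7"), 2)
  expect_equal(h$tau_m, c(5, -10))
  expect_equal(h$tau_s, c(2, 1))
  expect_equal(h$alpha, 0.5)
  expect_error(prior_spec(delta = c(0.5, -1)), "strictly positive")
})
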