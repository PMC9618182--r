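test_that("read_protein_table parses TSV, maps headers, treats zero as missing", {
  df <- data.frame(accession = c("P1", "P2", "P3"),
                   symbol = c("A", "B", "C"),
                   unique_peptides = c(3L, 2L, 5L),
                   case = c(10, 0, 30), ctrl = c(5, 15, 25))
  path <- write_tsv_fixture(df)
  tab <- read_protein_table(path, c("case", "ctrl"))
  expect_s3_class(tab, "protein_quant")
  expect_equal(nrow(tab), 3L)
  expect_true(is.na(tab$case[2]))  # zero intensity -> not detected
  expect_false(anyNA(tab$ctrl))

  # MaxQuant-style headers through col_map
  names(df) <- c("Majority protein IDs", "Gene names", "Unique peptides",
                 "Reporter intensity corrected 1",
                 "Reporter intensity corrected 2")
  path2 <- write_tsv_fixture(df)
  tab2 <- read_protein_table(
    path2, c("case", "ctrl"),
    col_map = c(accession = "Majority protein IDs",
                symbol = "Gene names",
                unique_peptides = "Unique peptides",
                case = "Reporter intensity corrected 1",
                ctrl = "Reporter intensity corrected 2"))
  expect_equal(tab2$accession, tab$accession)
  expect_equal(tab2$ctrl, tab$ctrl)
})

test_that("read_protein_table fails with named column on malformed input", {
  df <- data.frame(accession = c("P1", "P2"), symbol = c("A", "B"),
                   unique_peptides = c(2L, 2L), case = c(1, 2))
  path <- write_tsv_fixture(df)
  expect_error(read_protein_table(path, c("case", "ctrl")), "ctrl")
  df2 <- data.frame(accession = c("P1", "P1"), symbol = c("A", "B"),
                    unique_peptides = c(2L, 2L),
                    case = c(1, 2), ctrl = c(1, 2))
  expect_error(read_protein_table(write_tsv_fixture(df2),
                                  c("case", "ctrl")),
               "duplicate accession")
  expect_error(read_protein_table(tempfile(), "case"), "not found")
})

test_that("filter retains >=2-peptide fully-detected proteins with a reconciled report", {
  # 100 rows: 10 forced to 1 peptide, 5 disjoint rows given a missing value
  intens <- matrix(runif(200, 1, 10), ncol = 2,
                   dimnames = list(NULL, c("case", "ctrl")))
  pep <- rep(3L, 100)
  pep[1:10] <- 1L
  intens[11:15, 1] <- NA
  tab <- make_table(intens, unique_peptides = pep)
  res <- filter_analysis_ready(tab)
  expect_equal(res$report,
               list(n_input = 100L, n_fail_peptides = 10L,
                    n_fail_missing = 5L, n_retained = 85L))
  expect_equal(nrow(res$table), 85L)
  expect_true(all(res$table$unique_peptides >= 2L))
  expect_false(anyNA(res$table$case))

  # a row failing both rules is attributed to both counters,
  # reconciliation via the union
  intens2 <- intens
  intens2[1, 1] <- NA
  tab2 <- make_table(intens2, unique_peptides = pep)
  rep2 <- filter_analysis_ready(tab2)$report
  expect_equal(rep2$n_fail_peptides, 10L)
  expect_equal(rep2$n_fail_missing, 6L)
  expect_equal(rep2$n_retained, 85L)
})

test_that("filter is idempotent, order-independent and identity on clean tables", {
  set.seed(7)
  intens <- matrix(runif(120, 1, 10), ncol = 3,
                   dimnames = list(NULL, c("p1", "p2", "p3")))
  pep <- sample(c(1L, 2L, 5L), 40, replace = TRUE)
  intens[sample(40, 6), 2] <- NA
  tab <- make_table(intens, unique_peptides = pep)

  once <- filter_analysis_ready(tab)
  twice <- filter_analysis_ready(once$table)
  expect_equal(twice$table, once$table)
  expect_equal(twice$report$n_fail_peptides, 0L)
  expect_equal(twice$report$n_fail_missing, 0L)

  perm <- sample(nrow(tab))
  shuffled <- validate_protein_table(tab[perm, ], attr(tab, "pools"))
  expect_setequal(filter_analysis_ready(shuffled)$table$accession,
                  once$table$accession)

  clean <- make_table(matrix(runif(20, 1, 5), ncol = 2,
                             dimnames = list(NULL, c("a", "b"))),
                      unique_peptides = rep(2L, 10))
  expect_equal(filter_analysis_ready(clean)$table$accession,
               clean$accession)
})
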