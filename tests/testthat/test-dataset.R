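test_that("FASTA reading handles wrapping, ids, case and duplicates", {
  set.seed(111)
  recs <- list(P1 = random_protein(55), P2 = tolower(random_protein(73)))
  path <- write_toy_fasta(recs, wrap = 10)
  got <- read_fasta(path)
  expect_length(got, 2L)
  expect_equal(nchar(got[["P1"]]), 55L)
  expect_equal(got[["P2"]], toupper(recs$P2))

  # header token is cut at the first whitespace
  path2 <- tempfile(fileext = ".fasta")
  writeLines(c(">P9 some description here", "ACDEFG"), path2)
  expect_equal(names(read_fasta(path2)), "P9")

  # empty file -> empty mapping
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_fasta(empty), 0L)

  # duplicate id: last record wins, with a warning
  path3 <- tempfile(fileext = ".fasta")
  writeLines(c(">D1", "AAAA", ">D1", "CCCC"), path3)
  expect_warning(got3 <- read_fasta(path3), "duplicate")
  expect_equal(unname(got3["D1"]), "CCCC")

  # sequence before any header is a line-numbered parse error
  path4 <- tempfile(fileext = ".fasta")
  writeLines(c("ACDEF", ">X1", "GGG"), path4)
  expect_error(read_fasta(path4), "line 1")
})

test_that("pair lists parse tabs/spaces, headers and malformed lines", {
  p <- tempfile()
  writeLines(c("A1\tB1", "A2  B2", "A3 B3"), p)
  recs <- read_pairs(p, label = 1L)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$id_a, c("A1", "A2", "A3"))
  expect_true(all(recs$label == 1L))

  ph <- tempfile()
  writeLines(c("proteinA proteinB", "X1 Y1", "X2 Y2"), ph)
  expect_message(rh <- read_pairs(ph, label = 0L), "header")
  expect_equal(nrow(rh), 2L)
  expect_true(all(rh$label == 0L))

  pb <- tempfile()
  writeLines(c("A1 B1", "A2 B2 C2"), pb)
  expect_error(read_pairs(pb, label = 1L), "line 2")
})

test_that("filtering removes each exclusion category and reports counts", {
  set.seed(121)
  seqs <- c(
    P1 = random_protein(60), P2 = random_protein(70),
    P3 = random_protein(80), P4 = random_protein(90),
    SHORT = random_protein(30),
    ODD = paste0(random_protein(50), "U", random_protein(49))
  )
  records <- data.frame(
    id_a = c("P1", "P2", "P3", "P3", "P1", "P2", "MISSING"),
    id_b = c("P2", "P3", "P3", "P4", "SHORT", "ODD", "P1"),
    label = c(1L, 1L, 1L, 1L, 0L, 0L, 0L)
  )
  # add a reversed duplicate of (P1, P2)
  records <- rbind(records, data.frame(id_a = "P2", id_b = "P1", label = 1L))
  out <- filter_records(records, seqs)
  expect_equal(unname(out$report["input"]), 8L)
  expect_equal(unname(out$report["missing_sequence"]), 1L)
  expect_equal(unname(out$report["self_interaction"]), 1L)
  expect_equal(unname(out$report["duplicate"]), 1L)
  expect_equal(unname(out$report["too_short"]), 1L)
  expect_equal(unname(out$report["unusual_residue"]), 1L)
  expect_equal(unname(out$report["output"]), 3L)
  # exclusions account exactly for the removed rows
  excl <- sum(out$report[c("missing_sequence", "self_interaction",
                           "duplicate", "unusual_residue", "too_short",
                           "composition_collision")])
  expect_equal(unname(out$report["input"] - out$report["output"]), excl)
  # idempotent
  again <- filter_records(out$records, seqs)
  expect_equal(again$records, out$records)
  expect_equal(unname(again$report["output"]),
               unname(out$report["output"]))
})

test_that("the collision filter drops equal-length equal-composition pairs", {
  seqs <- c(
    E1 = strrep("ACDEG", 12), # 60 residues
    E2 = paste(rev(strsplit(strrep("ACDEG", 12), "")[[1]]), collapse = ""),
    F1 = random_protein(61)
  )
  records <- data.frame(id_a = c("E1", "E2"), id_b = c("E2", "F1"),
                        label = c(1L, 0L))
  off <- filter_records(records, seqs, collision_filter = FALSE)
  expect_equal(unname(off$report["output"]), 2L)
  on <- filter_records(records, seqs, collision_filter = TRUE)
  expect_equal(unname(on$report["composition_collision"]), 1L)
  expect_equal(on$records$id_a, "E2")
})

test_that("pair tables concatenate per-protein vectors at the pair dim", {
  set.seed(131)
  seqs <- setNames(vapply(1:6, function(i) random_protein(60), character(1)),
                   paste0("P", 1:6))
  records <- data.frame(id_a = c("P1", "P3", "P5"),
                        id_b = c("P2", "P4", "P6"),
                        label = c(1L, 1L, 0L))
  tab <- build_pair_table(records, seqs, "MOS")
  expect_s3_class(tab, "pair_feature_table")
  expect_equal(dim(tab$x), c(3L, 58L))
  expect_equal(tab$n_pos + tab$n_neg, 3L)
  # (a, b) order: first 29 columns are protein a's features
  expect_equal(unname(tab$x[1, 1:29]), unname(encode_mos(seqs[["P1"]])))
  expect_equal(unname(tab$x[1, 30:58]), unname(encode_mos(seqs[["P2"]])))

  expect_equal(ncol(build_pair_table(records, seqs, "CT")$x), 686L)

  # pairs whose proteins cannot be encoded are skipped and counted
  seqs2 <- c(seqs, TINY = random_protein(25))
  records2 <- rbind(records,
                    data.frame(id_a = "P1", id_b = "TINY", label = 0L))
  expect_warning(tab2 <- build_pair_table(records2, seqs2, "AC"), "skipped")
  expect_equal(nrow(tab2$x), 3L)
  expect_equal(tab2$n_skipped, 1L)
})

test_that("train/holdout splits are stratified, disjoint and seeded", {
  tab <- separable_table(n_per_class = 100L, dim = 8L, seed = 5)
  sp <- split_train_holdout(tab, 60L, 60L, seed = 9L)
  expect_equal(nrow(sp$train$x), 120L)
  expect_equal(nrow(sp$holdout$x), 80L)
  expect_equal(sp$train$n_pos, 60L)
  expect_equal(sp$train$n_neg, 60L)
  expect_length(intersect(rownames(sp$train$x), rownames(sp$holdout$x)), 0L)
  expect_setequal(c(rownames(sp$train$x), rownames(sp$holdout$x)),
                  rownames(tab$x))
  sp2 <- split_train_holdout(tab, 60L, 60L, seed = 9L)
  expect_identical(sp$train$x, sp2$train$x) # same seed, same split
  expect_error(split_train_holdout(tab, 101L, 50L, seed = 1L),
               "101 positive")
})
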