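test_that("toy PDB with four role chains parses to the expected residues", {
  cs <- parse_structure(toy_pdb_text(n_res = 5), toy_roles(),
                        complex_id = "toy") |> suppressWarnings()
  expect_s3_class(cs, "complex_structure")
  rt <- tcrgraphs:::residue_table(cs)
  expect_equal(nrow(rt), 20)
  expect_setequal(unique(rt$chain_id), c("M", "P", "A", "B"))
  expect_true(all(table(rt$chain_id) == 5))
  expect_true(all(cs$atoms$element != "H"))
})

test_that("residue counts match an independent line-by-line PDB scan", {
  for (n in c(4, 7, 9)) {
    txt <- toy_pdb_text(n_res = n)
    cs <- suppressWarnings(parse_structure(txt, toy_roles()))
    # naive oracle: substring-parse ATOM lines directly
    lines <- grep("^ATOM", strsplit(txt, "\n")[[1]], value = TRUE)
    chain <- substr(lines, 22, 22)
    resno <- as.integer(substr(lines, 23, 26))
    oracle <- tapply(resno, chain, function(v) length(unique(v)))
    got <- table(tcrgraphs:::residue_table(cs)$chain_id)
    expect_equal(as.integer(got[names(oracle)]), as.integer(oracle))
  }
})

test_that("alternate locations keep the highest-occupancy conformer", {
  base <- strsplit(toy_pdb_text(n_res = 8), "\n")[[1]]
  # duplicate the first CA of chain M with altlocs A (0.6) / B (0.4)
  i <- grep("^ATOM.* CA .*ALA M", base)[1]
  lA <- base[i]; substr(lA, 17, 17) <- "A"
  lB <- base[i]; substr(lB, 17, 17) <- "B"
  substr(lA, 55, 60) <- "  0.60"
  substr(lB, 55, 60) <- "  0.40"
  # move altloc B so the choice is observable in coordinates
  substr(lB, 31, 38) <- sprintf("%8.3f", 99.0)
  txt <- paste(c(base[seq_len(i - 1)], lA, lB, base[(i + 1):length(base)]),
               collapse = "\n")
  cs <- suppressWarnings(parse_structure(txt, toy_roles()))
  ca1 <- cs$atoms[cs$atoms$chain_id == "M" & cs$atoms$res_seq == 1 &
                    cs$atoms$atom_name == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 0)           # altloc A retained
  expect_equal(ca1$occupancy, 0.6)
})

test_that("missing role chains and non-standard residues are handled", {
  txt <- toy_pdb_text()
  no_b <- paste(grep(" B ", strsplit(txt, "\n")[[1]],
                     invert = TRUE, value = TRUE), collapse = "\n")
  expect_error(suppressWarnings(parse_structure(no_b, toy_roles())), "TCRB")
  # MSE maps to MET, unknown residue dropped with warning
  lines <- strsplit(txt, "\n")[[1]]
  lines <- sub("ALA M   1", "MSE M   1", lines)
  lines <- sub("ALA P   2", "XYZ P   2", lines)
  cs <- suppressWarnings(parse_structure(paste(lines, collapse = "\n"),
                                         toy_roles()))
  suppressWarnings(
    expect_warning(parse_structure(paste(lines, collapse = "\n"), toy_roles()),
                   "XYZ"))
  rt <- tcrgraphs:::residue_table(cs)
  expect_true("MET" %in% rt$res_name[rt$chain_id == "M"])
  expect_false(2 %in% rt$res_seq[rt$chain_id == "P"])
})

test_that("parse -> write -> parse preserves residues and coordinates", {
  cs <- simulate_complex("strong", synthetic_spec(), seed = 77)
  tf <- tempfile(fileext = ".pdb")
  write_structure(cs, tf)
  cs2 <- parse_structure(readLines(tf), cs$roles, complex_id = cs$complex_id)
  expect_equal(cs2$atoms$res_name, cs$atoms$res_name)
  expect_equal(cs2$atoms$res_seq, cs$atoms$res_seq)
  expect_equal(as.matrix(cs2$atoms[, c("x", "y", "z")]),
               as.matrix(cs$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
})

test_that("Kd labelling follows the 200 uM threshold with weak boundary", {
  expect_equal(label_from_kd(100), "strong")
  expect_equal(label_from_kd(300), "weak")
  expect_equal(label_from_kd(200), "weak")
  expect_error(label_from_kd(-1))
  expect_error(label_from_kd(Inf))
  set.seed(1)
  kds <- 10^runif(1000, -2, 4)
  expect_equal(vapply(kds, label_from_kd, character(1)),
               ifelse(kds < 200, "strong", "weak"))
})

test_that("log50k transform matches its defining inequality", {
  b <- log50k_score(500)
  expect_equal(b$score, 0.4256, tolerance = 1e-4)
  expect_false(b$binder)  # boundary is non-binder
  expect_equal(log50k_score(50000)$score, 0)
  expect_equal(log50k_score(1)$score, 1)
  expect_true(log50k_score(1)$binder)
  set.seed(2)
  ic <- 10^runif(1000, 0.01, 4.69)
  got <- vapply(ic, function(v) log50k_score(v)$binder, logical(1))
  expect_equal(got, ic < 500)
  # strictly decreasing on (1, 50000)
  sc <- vapply(sort(ic), function(v) log50k_score(v)$score, numeric(1))
  expect_true(all(diff(sc) < 0))
  expect_gt(min(sc[ic < 500]), 0)
})

test_that("role and affinity CSVs round-trip with label derivation", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("complex_id,chain_id,role",
               "c1,M,MHC", "c1,P,PEPTIDE", "c1,A,TCRA", "c1,B,TCRB",
               "c1,Q,OTHER"), tf)
  roles <- read_chain_roles(tf)
  expect_equal(unname(roles$c1["P"]), "PEPTIDE")
  ta <- tempfile(fileext = ".csv")
  writeLines(c("complex_id,kd_uM,ic50_nM,label",
               "c1,50,,", "c2,1000,,", "c3,,200,", "c4,,,strong"), ta)
  aff <- read_affinities(ta)
  expect_equal(aff$label, c("strong", "weak", NA, "strong"))
  tb <- tempfile(fileext = ".csv")
  writeLines(c("complex_id,kd_uM,ic50_nM,label", "c9,,,"), tb)
  expect_error(read_affinities(tb), "c9")
})
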