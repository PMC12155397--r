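test_that("pseudoatoms follow the Q/QX/QQX naming rules", {
  f <- build_fixture("valine_residue")
  ps <- build_pseudoatoms(f$ensemble$atoms)
  get <- function(nm) ps[ps$name == nm, ]
  expect_equal(get("QG1")$n, 3L)
  expect_equal(get("QG2")$n, 3L)
  expect_equal(get("QQG")$n, 6L)
  expect_setequal(f$ensemble$atoms$name[get("QQG")$parents[[1]]],
                  c(paste0("HG1", 1:3), paste0("HG2", 1:3)))
  # glycine CH2: QA from the two present parents only
  g <- build_fixture("gly_dipeptide")
  psg <- build_pseudoatoms(g$ensemble$atoms)
  qa <- psg[psg$name == "QA" & psg$resno == 1L, ]
  expect_equal(qa$n, 2L)
  expect_setequal(g$ensemble$atoms$name[qa$parents[[1]]], c("HA2", "HA3"))
  # Q from H1/H2/H3 after terminus fixing
  sys <- prepare_system(build_fixture("ala_tripeptide")$ensemble)
  pst <- build_pseudoatoms(sys$ensemble$atoms)
  q <- pst[pst$name == "Q" & pst$resno == 1L, ]
  expect_equal(q$n, 3L)
  # QB from a full methyl
  expect_equal(pst[pst$name == "QB" & pst$resno == 2L, ]$n, 3L)
})

test_that("parse_upl handles the 7-column dialect, comments and junk", {
  parsed <- parse_upl(c("12 ALA QB 45 LEU H 4.50",
                        "# comment line",
                        "",
                        "12 ALA QB 45   # truncated",
                        " 3 GLY HA2  7 VAL QQG  5.20  1.00 # weight"))
  expect_equal(nrow(parsed$entries), 2L)
  e <- parsed$entries[1, ]
  expect_equal(e$resno_i, 12L)
  expect_identical(e$resname_i, "ALA")
  expect_identical(e$name_i, "QB")
  expect_equal(e$resno_j, 45L)
  expect_identical(e$name_j, "H")
  expect_equal(e$rp, 4.5)
  expect_equal(parsed$entries$line, c(1L, 5L))
  expect_equal(nrow(parsed$bad), 1L)
  expect_identical(parsed$bad$reason, "parse error")
})

test_that("pseudoatom correction reproduces r_p * N^(1/6)", {
  # frozen against an independently evaluated power function
  expect_identical(correct_pseudoatom_distance(4.5, 1, 1), 4.5)
  expect_equal(correct_pseudoatom_distance(4.5, 3, 1), 5.4042163,
               tolerance = 1e-7)
  expect_equal(correct_pseudoatom_distance(4.5, 3, 3), 6.4901232,
               tolerance = 1e-7)
  expect_equal(correct_pseudoatom_distance(1, 2, 1), 1.1224620,
               tolerance = 1e-7)
  expect_equal(correct_pseudoatom_distance(1, 6, 1), 1.3480061,
               tolerance = 1e-7)
  expect_equal(correct_pseudoatom_distance(1, 9, 1), 1.4422496,
               tolerance = 1e-7)
  # monotone in each argument
  expect_true(all(diff(correct_pseudoatom_distance(2.5, 1:6, 2)) > 0))
  expect_error(correct_pseudoatom_distance(-1, 1, 1), "positive")
  expect_error(correct_pseudoatom_distance(4, 0, 1), ">= 1")
})

test_that("resolution conserves entries and reports unknown atoms", {
  sys <- prepare_system(build_fixture("ala_tripeptide")$ensemble)
  at <- sys$ensemble$atoms
  upl <- c("1 ALA HA 3 ALA H 5.0",      # real atoms
           "2 ALA QB 3 ALA HA 4.0",     # pseudoatom x real
           "1 ALA Q25 3 ALA H 4.0",     # opaque pseudoatom name
           "junk line here",
           "2 ALA QB 2 ALA QB 4.0")     # self pair (kept)
  parsed <- parse_upl(upl)
  rset <- resolve_restraints(parsed$entries, at, bad = parsed$bad)
  expect_equal(nrow(rset$restraints) + nrow(rset$unresolved), 5L)
  expect_equal(nrow(rset$restraints), 3L)
  expect_identical(rset$unresolved$reason,
                   c("parse error", "unknown atom Q25 in residue 1"))
  r1 <- rset$restraints[1, ]
  expect_equal(r1$r_corrected, r1$rp)          # single atoms: identity
  r2 <- rset$restraints[2, ]
  expect_equal(r2$r_corrected, 4.0 * 3^(1/6))  # methyl endpoint
  # order independence
  rset_rev <- resolve_restraints(
    parsed$entries[rev(seq_len(nrow(parsed$entries))), ], at,
    bad = parsed$bad)
  expect_setequal(rset_rev$restraints$line, rset$restraints$line)
  # residue-name mismatch warns but matches
  p2 <- parse_upl("1 GLY HA 3 ALA H 5.0")
  expect_warning(r <- resolve_restraints(p2$entries, at), "GLY")
  expect_equal(nrow(r$restraints), 1L)
})

test_that("restraints.log carries one line per unresolved entry", {
  sys <- prepare_system(build_fixture("ala_tripeptide")$ensemble)
  rset <- read_upl(c("1 ALA HA 3 ALA H 5.0", "9 ALA QZ 1 ALA HA 3.0"),
                   sys$ensemble$atoms)
  log <- withr::local_tempfile(fileext = ".log")
  write_restraint_log(rset, log)
  lines <- readLines(log)
  expect_length(lines, 1L)
  expect_match(lines, "unknown atom QZ in residue 9")
})
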