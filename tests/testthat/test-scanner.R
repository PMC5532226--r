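test_that("find_heptapeptides detects canonical and variant 7-mers", {
  hits <- find_heptapeptides("AAWRKYGQKAA")
  expect_identical(hits$position, 2L)
  expect_identical(hits$sequence, "WRKYGQK")
  expect_identical(hits$hamming, 0L)

  expect_identical(find_heptapeptides("WRKYGEK")$hamming, 1L)  # printed variant
  expect_identical(find_heptapeptides("CRKYGQA")$hamming, 2L)  # largest variant
  expect_identical(nrow(find_heptapeptides("CRKYGQA", max_mismatch = 1)), 0L)
  expect_error(find_heptapeptides("WRKYGQ1"), "invalid protein")
})

test_that("overlapping heptapeptide hits keep the lower distance, ties leftmost", {
  # WRKYGQKYGQK: window at 0 exact; window at 4 'GQKYGQK' is far; craft overlap
  s <- "WRKYGQWRKYGQK"   # hit at 6 exact (hamming 0), window at 0 has hamming 2
  hits <- find_heptapeptides(s)
  expect_identical(hits$position, 6L)
  expect_identical(hits$hamming, 0L)
  # tie: two overlapping hamming-0 hits cannot exist; check tie at equal distance
  s2 <- "WRKYGQWRKYGQW"  # windows at 0 and 6 both hamming 2 (overlap): leftmost
  hits2 <- find_heptapeptides(s2)
  expect_identical(hits2$position, 0L)
})

test_that("find_zinc_finger types C2H2/C2HC and reports literal spacers", {
  mk <- function(m, n, last) paste0(
    strrep("A", 3), "C", strrep("A", m), "C", strrep("G", n), "H", "A", last)
  zf <- find_zinc_finger(mk(4, 23, "H"), start = 0)
  expect_identical(zf$zf_type, "C2H2")
  expect_identical(c(zf$m, zf$n), c(4L, 23L))
  zf2 <- find_zinc_finger(mk(4, 23, "C"), start = 0)
  expect_identical(zf2$zf_type, "C2HC")
  expect_null(find_zinc_finger(strrep("A", 60), start = 0))
  # reconstruction: reported positions carry exactly m and n residues between
  s <- mk(6, 24, "H")
  zf3 <- find_zinc_finger(s, 0)
  p <- zf3$positions + 1L
  expect_identical(substring(s, p[1], p[1]), "C")
  expect_identical(p[2] - p[1] - 1L, zf3$m)
  expect_identical(p[3] - p[2] - 1L, zf3$n)
})

test_that("extended mode reaches the C-X5-C-X88 arrangement", {
  s <- paste0("WRKYGQK", "AAA", "C", strrep("A", 5), "C", strrep("G", 88),
              "HAH", "AAAA")
  expect_null(find_zinc_finger(s, 7, scan_config()))
  zf <- find_zinc_finger(s, 7, scan_config(extended = TRUE))
  expect_identical(c(zf$m, zf$n), c(5L, 88L))
})

test_that("scan_protein pairs heptapeptides with fingers and labels terminals", {
  dom <- function(m = 4, n = 23, last = "H")
    paste0("WRKYGQK", "GGGGG", "C", strrep("A", m), "C", strrep("G", n),
           "HA", last)
  two <- paste0("MET", dom(4, 22), "KKKK", dom(4, 23), "VVV")
  sc <- scan_protein(c(gene = two))
  expect_identical(nrow(sc), 2L)
  expect_identical(sc$terminal, c("N", "C"))
  expect_true(all(sc$complete))
  expect_identical(sc$n, c(22L, 23L))

  # N-terminal complete + C-terminal heptapeptide without finger
  inc <- paste0("MET", dom(), "KKKK", "WRKYGQK", "AAAA")
  sc2 <- scan_protein(c(g2 = inc))
  expect_identical(sc2$complete, c(TRUE, FALSE))
  expect_identical(sc2$terminal, c("N", "C"))

  expect_identical(nrow(scan_protein(c(g3 = strrep("ADEF", 30)))), 0L)
  one <- scan_protein(c(g4 = paste0("MET", dom())))
  expect_identical(one$terminal, "only")
})

test_that("compute_physchem matches closed-form mass and charge signs", {
  expect_equal(compute_physchem("G")$mw, 75.067, tolerance = 1e-3)
  # dipeptide: two residues + one water
  expect_equal(compute_physchem("GG")$mw, 2 * 57.0519 + 18.01524,
               tolerance = 1e-3)
  expect_lt(compute_physchem("DDEE")$pI, 7)
  expect_gt(compute_physchem("KKRR")$pI, 7)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(compute_physchem(s)$pI, compute_physchem(perm)$pI,
               tolerance = 1e-9)
  expect_error(compute_physchem("MKX"), "ambiguous")
})

test_that("scanning planted families recovers every planted domain exactly", {
  fam <- make_family(40, variant_rate = 0.15, seed = 2024)
  sc <- scan_proteins(fam$proteins)
  expect_true(all(sc$hamming <= 2))
  for (i in seq_len(nrow(fam$truth))) {
    t <- fam$truth[i, ]
    d <- sc[sc$gene_id == t$gene_id, ]
    expected_heps <- na.omit(c(t$hepta_1, t$hepta_2))
    expect_identical(d$heptapeptide, as.character(expected_heps))
    planted_zf <- na.omit(c(t$zf_1, t$zf_2))
    expect_identical(d$zf_type[d$complete], as.character(planted_zf))
    expect_identical(d$m[d$complete],
                     as.integer(na.omit(c(t$m_1, t$m_2))))
    expect_identical(d$n[d$complete],
                     as.integer(na.omit(c(t$n_1, t$n_2))))
  }
})

test_that("scan results are deterministic and independent of record order", {
  fam <- make_family(10, seed = 77)
  sc1 <- scan_proteins(fam$proteins)
  sc2 <- scan_proteins(rev(fam$proteins))
  sc2 <- sc2[order(match(sc2$gene_id, sc1$gene_id), sc2$domain_index), ]
  rownames(sc2) <- NULL
  expect_identical(sc1, sc2)
})
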