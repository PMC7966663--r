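# MSA tail classification, conservation partitioning, motif census and tail
# physicochemistry.

# small hand-checkable alignment: reference 1-10, anchors shifted to 4:6
tiny_msa <- function() {
  anchored_msa(c(
    REF = "ACDEFGHIKL",
    s1  = "ACDEFGHIKL",   # tailed (letters at 4:6)
    s2  = "ACD---HIKL",   # untailed at anchors 4:6
    s3  = "ACDE-GHIKL",   # one gap among the anchors
    s4  = "GCDLSLHIKL"    # tailed, LSL at 4:6
  ), reference_id = "REF")
}

test_that("anchored MSA construction validates and maps columns", {
  msa <- tiny_msa()
  expect_equal(unname(msa$column_map), 1:10)
  expect_error(anchored_msa(c(a = "AC-", b = "ACDE")), "equal length")
  expect_error(anchored_msa(c(a = "AC-"), reference_id = "zz"), "not found")
  # gapped reference maps only its non-gap columns
  m2 <- anchored_msa(c(r = "A-CD", x = "ABCD"), reference_id = "r")
  expect_equal(unname(m2$column_map), c(1, 3, 4))
})

test_that("tail classification requires all anchor columns by default", {
  msa <- tiny_msa()
  tl <- classify_tail(msa, positions = 4:6)
  expect_equal(unname(tl[c("s1", "s2", "s3", "s4")]),
               c(TRUE, FALSE, FALSE, TRUE))
  # permissive 'any' reading differs exactly on the partially-gapped row
  ta <- classify_tail(msa, positions = 4:6, mode = "any")
  expect_equal(unname(ta[["s3"]]), TRUE)
  expect_equal(sum(tl) + sum(!tl), length(msa$ids))
  expect_error(classify_tail(msa, positions = 183:185), "lacks residues")
})

test_that("conservation matches hand counts, excluding gaps", {
  msa <- tiny_msa()
  cons <- conservation(msa, "all")
  # position 1: A,A,A,A,G -> A 4/5
  expect_equal(cons$frequency[cons$position == 1], 0.8)
  expect_equal(cons$consensus[cons$position == 1], "A")
  # position 5: F,F,-,-,S -> F 2/3 non-gap, gap fraction 2/5
  expect_equal(cons$frequency[cons$position == 5], 2 / 3)
  expect_equal(cons$gap_fraction[cons$position == 5], 0.4)
  # tie flagged and broken alphabetically: position 4 has E,E,-,E,L? no;
  # construct a 50/50 column directly
  m <- anchored_msa(c(r = "AA", x = "KA", y = "RA"), reference_id = "r")
  c2 <- conservation(m, "all")
  expect_true(c2$tie[c2$position == 1])
  expect_equal(c2$consensus[c2$position == 1], "A")  # A,K,R all 1/3 -> A
})

test_that("conservation is invariant to row order and duplication", {
  msa <- gen_msa(n = 60, tail_fraction = 0.3, seed = 9)
  cons <- conservation(msa, "all")
  perm <- msa
  ord <- sample(length(perm$sequences))
  perm$sequences <- perm$sequences[ord]; perm$ids <- perm$ids[ord]
  expect_equal(conservation(perm, "all")$frequency, cons$frequency)
  dup <- msa
  dd <- stats::setNames(msa$sequences, paste0(msa$ids, "_dup"))
  dup$sequences <- c(msa$sequences, dd)
  dup$ids <- names(dup$sequences)
  expect_equal(conservation(dup, "all")$frequency, cons$frequency)
})

test_that("tail-specific conservation surfaces the constructed position", {
  msa <- gen_msa(n = 400, tail_fraction = 0.25, conserved_position = 100,
                 seed = 13)
  tsc <- tail_specific_conservation(msa)
  expect_equal(tsc$position[1], 100)
  expect_gt(tsc$difference[1], 0.5)
  # identical partitions give all-zero differences
  m <- anchored_msa(c(r = "ACDEF", a = "ACDEF", b = "ACDEF"))
  # all rows tailed at default anchors? use positions 1:3 present everywhere
  t2 <- conservation(m, "all")
  expect_true(all(t2$frequency == 1))
})

test_that("motif census equals the per-row regexp oracle", {
  for (s in c(2, 3)) {
    msa <- gen_msa(n = 300, tail_fraction = 0.4, seed = s)
    cen <- motif_census(msa)
    oracle <- census_oracle(msa)
    expect_equal(cen$counts[names(oracle)], oracle)
    # class counts never exceed the tailed total
    expect_true(all(cen$counts <= cen$counts[["total_tailed"]]))
    # disjoint classes at one position sum within the total
    expect_lte(cen$counts[["aliphatic_183"]] + cen$counts[["aromatic_183"]],
               cen$counts[["total_tailed"]])
  }
  # constructed micro-census
  m <- anchored_msa(c(
    REF = paste0(strrep("A", 182), "LSLAAAAA"),
    h1  = paste0(strrep("A", 182), "LSLAAAAA"),
    h2  = paste0(strrep("A", 182), "LTLAAAAA"),
    h3  = paste0(strrep("A", 182), "FRQAAAAA"),
    h4  = paste0(strrep("A", 182), "IS-AAAAA")
  ), reference_id = "REF")
  cen <- motif_census(m)
  expect_equal(unname(cen$counts[["lsl_complete"]]), 1)  # h1 (REF not counted)
  expect_equal(unname(cen$counts[["aliphatic_183"]]), 2) # h1 (L), h2 (L)
  expect_equal(unname(cen$counts[["total_tailed"]]), 3)  # h4 gapped at 185
  # an alignment whose homologs all lack tails gives an empty census
  expect_warning(
    cen0 <- motif_census(gen_msa(n = 20, tail_fraction = 0, seed = 4)),
    "empty")
  expect_equal(unname(cen0$counts[["total_tailed"]]), 0)
})

test_that("pfm columns are probability vectors with gap bookkeeping", {
  msa <- gen_msa(n = 150, tail_fraction = 0.5, seed = 17)
  p <- pfm(msa, 176:190, "tailed")
  sums <- colSums(p)
  expect_equal(unname(sums), rep(1, ncol(p)), tolerance = 1e-12)
  expect_true(all(dim(p) == c(20, 15)))
  # single sequence gives one-hot columns
  m1 <- anchored_msa(c(only = "ACD"))
  p1 <- pfm(m1, 1:3, "all")
  expect_equal(unname(colSums(p1 == 1)), rep(1, 3))
  # untailed rows are all-gap across the tail: flagged
  msa2 <- gen_msa(n = 50, tail_fraction = 0, seed = 1)
  p2 <- pfm(msa2, 184, "all")  # only REF has a residue there
  expect_equal(unname(colSums(p2, na.rm = TRUE)), 1)
})

test_that("tail properties compute charge and Kyte-Doolittle hydropathy", {
  expect_equal(tail_properties("DE")$net_charge, -2)
  expect_equal(tail_properties("KRH")$net_charge, 2)  # His neutral
  expect_equal(unname(tail_properties("I", window = 1)$hydropathy), 4.5)
  # charge additivity over concatenation
  set.seed(3)
  for (i in 1:5) {
    a <- paste(sample(c("A", "K", "R", "D", "E", "H", "S"), 8, TRUE),
               collapse = "")
    b <- paste(sample(c("G", "K", "D", "L", "Y"), 6, TRUE), collapse = "")
    expect_equal(tail_properties(paste0(a, b))$net_charge,
                 tail_properties(a)$net_charge + tail_properties(b)$net_charge)
  }
  # window means truncate at the edges
  tp <- tail_properties("IVL", window = 5)
  expect_equal(unname(tp$hydropathy[2]), mean(c(4.5, 4.2, 3.8)))
  expect_error(tail_properties("AXZ"), "X")
  expect_error(tail_properties("AA", window = 2), "odd")
})

test_that("alignment files round-trip through the readers", {
  msa <- tiny_msa()
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(msa$sequences), function(id)
    c(paste0(">", id), msa$sequences[[id]]))), fa)
  rt <- read_anchored_msa(fa, reference_id = "REF")
  expect_equal(rt$sequences, msa$sequences)
  expect_equal(rt$column_map, msa$column_map)
  # a3m: lowercase insert states are dropped
  a3m <- tempfile(fileext = ".a3m")
  writeLines(c(">REF", "ACDEF", ">x", "ACdeDEF"), a3m)
  ra <- read_anchored_msa(a3m, reference_id = "REF")
  expect_equal(unname(ra$sequences[["x"]]), "ACDEF")
})
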