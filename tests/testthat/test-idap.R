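test_that("find_summits detects thresholded maxima and suppresses near neighbours", {
  s <- find_summits(c(0, 1, 5, 1, 0), min_height = 2)
  expect_equal(s$position, 2)
  expect_equal(s$height, 5)

  expect_identical(nrow(find_summits(rep(0, 50), min_height = 1)), 0L)
  expect_identical(nrow(find_summits(c(0, 1, 1, 0), min_height = 2)), 0L)

  two_close <- c(rep(0, 10), 5, rep(0, 4), 5, rep(0, 10))
  expect_identical(nrow(find_summits(two_close, 2, min_separation = 10)), 1L)
  two_far <- c(rep(0, 10), 5, rep(0, 300), 5, rep(0, 10))
  expect_identical(nrow(find_summits(two_far, 2, min_separation = 10)), 2L)
})

test_that("plateau summits resolve to the directional edge", {
  # flat top against a cliff: the signature of containment end counts
  counts <- c(rep(0, 20), 1:5, rep(9, 30), rep(0, 40))
  up <- find_summits(counts, 2, tie_break = "rightmost")
  expect_equal(up$position, 54)  # last of the plateau
  lo <- find_summits(rev(counts), 2, tie_break = "leftmost")
  expect_equal(lo$position, length(counts) - 1 - 54)
  # noise on the flat top does not move the summit off the cliff edge
  noisy <- counts
  noisy[30] <- 12  # a noise spike inside the plateau
  expect_equal(find_summits(noisy, 2, tie_break = "rightmost")$position, 54)
})

test_that("pair_summits brackets sites within the gap bounds and reports leftovers", {
  up <- data.frame(position = 100, height = 50)
  lo <- data.frame(position = 115, height = 40)
  calls <- pair_summits(up, lo)
  expect_equal(calls$site_start, 100)
  expect_equal(calls$site_end, 115)
  expect_equal(calls$length, 16)
  expect_equal(calls$height, 40)

  lo_far <- data.frame(position = 300, height = 40)
  none <- pair_summits(up, lo_far)
  expect_identical(nrow(none), 0L)
  un <- attr(none, "unpaired")
  expect_equal(un$upper$position, 100)
  expect_equal(un$lower$position, 300)

  # circular pairing across the origin
  upw <- data.frame(position = 995, height = 10)
  low <- data.frame(position = 8, height = 10)
  cw <- pair_summits(upw, low, genome_length = 1000, circular = TRUE)
  expect_equal(cw$length, 14)
})

test_that("exhaustive-fragment pipeline matches the brute-force oracle exactly", {
  fr <- enumerate_containing_fragments(1000, 500, 16, c(50, 200))
  oracle <- oracle_site_call(fr, 1000)

  ends <- strand_end_counts(fr, 1000, circular = FALSE)
  us <- find_summits(ends$upper, 1, tie_break = "rightmost")
  ls <- find_summits(ends$lower, 1, tie_break = "leftmost")
  calls <- pair_summits(us, ls, 8, 40, 1000, FALSE)
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$site_start, unname(oracle["site_start"]))
  expect_equal(calls$site_end, unname(oracle["site_end"]))
  expect_equal(calls$site_start, 500)
  expect_equal(calls$site_end, 515)
  expect_equal(calls$length, 16)
})

test_that("site calling is rotation-equivariant", {
  L <- 2000
  fr <- enumerate_containing_fragments(L, 700, 16, c(50, 120))
  base <- oracle_site_call(fr, L)
  for (k in c(311, 1500)) {
    rot <- transform(fr, start = (start + k) %% L)
    ends <- strand_end_counts(rot, L, circular = TRUE)
    us <- find_summits(ends$upper, 1, tie_break = "rightmost", circular = TRUE)
    ls <- find_summits(ends$lower, 1, tie_break = "leftmost", circular = TRUE)
    calls <- pair_summits(us, ls, 8, 40, L, TRUE)
    expect_equal(calls$site_start, (base[["site_start"]] + k) %% L)
    expect_equal(calls$site_end, (base[["site_end"]] + k) %% L)
  }
})

test_that("call_sites subtracts the control and annotates calls", {
  g <- tiny_site_genome(circular = FALSE)
  fr <- simulate_idap_fragments(g, 320, 3000, seed = 8L)

  # control identical to the sample cancels everything
  expect_identical(nrow(call_sites(fr, fr, g)), 0L)
  expect_error(call_sites(fr[0, ], NULL, g), "empty")

  calls <- call_sites(fr, NULL, g, min_height = 5)
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$site_start, 5000)
  expect_equal(calls$site_end, 5015)
  expect_identical(calls$sequence, make_palindromic_site("GTGAAA", "ACGT"))
  expect_equal(calls$palindrome_score, 16)
})

test_that("calls never overlap and respect the gap bounds", {
  res <- study_seven_site_idap(seed = 3L, n = 4e4)
  calls <- res$calls
  expect_true(all(calls$length >= 8 & calls$length <= 40))
  if (nrow(calls) > 1) {
    o <- calls[order(calls$site_start), ]
    expect_true(all(o$site_start[-1] > o$site_end[-nrow(o)]))
  }
})

test_that("raising protein concentration raises weak-site call heights (paired seeds)", {
  g <- toy_genome(101L)
  weak_ids <- which(g$sites$kd >= 1000)
  heights <- function(conc, seed) {
    fr <- simulate_idap_fragments(g, conc, 3e4, background_prob = 0,
                                  seed = seed)
    calls <- call_sites(fr, NULL, g, min_height = 3)
    vapply(weak_ids, function(i) {
      j <- which(calls$site_start >= g$sites$start[i] - 5 &
                   calls$site_end <= g$sites$start[i] + 20)
      if (length(j)) max(calls$height[j]) else 0
    }, numeric(1))
  }
  for (seed in c(21L, 22L)) {
    h_low <- heights(100, seed)
    h_high <- heights(800, seed)
    expect_true(all(h_high >= h_low))
  }
})

test_that("palindrome scoring counts mirrored complementary positions", {
  expect_equal(palindrome_score("GAATTC"), 6)
  expect_equal(palindrome_score("AAAAAA"), 0)
  expect_equal(palindrome_score("TTTCACACGTGTGAAA"), 16)
  expect_error(palindrome_score("ACGN"), "A,C,G,T")
  expect_error(palindrome_score(""))

  # brute-force positionwise check against an independent loop
  brute <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    x <- strsplit(s, "")[[1]]
    n <- length(x)
    sum(vapply(seq_len(n), function(i) x[i] == comp[[x[n + 1 - i]]], logical(1)))
  }
  set.seed(9)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(4:20, 1), TRUE),
               collapse = "")
    expect_equal(palindrome_score(s), brute(s))
  }
})
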