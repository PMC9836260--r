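lex <- demo_lexicon()

test_that("polar clusters use a clipped 5-before/2-after window with pivot excluded", {
  expect_length(find_polar_clusters("we met in the lab", lex), 0)
  cl <- find_polar_clusters("good times and good vibes", lex)
  expect_length(cl, 2)
  # pivot at token 2 of a 4-token sentence clips to the full sentence
  cl <- find_polar_clusters("a good day here", lex)
  expect_equal(cl[[1]]$pivot_index, 2)
  expect_equal(cl[[1]]$window, c(1, 4))
  # shifters counted inside the window only, pivot excluded
  cl <- find_polar_clusters("not very good", lex)[[1]]
  expect_equal(cl$n_neg, 1)
  expect_equal(cl$n_amp, 1)
  # a shifter 6 tokens before the pivot is outside the window
  cl <- find_polar_clusters("not a b c d e good", lex)[[1]]
  expect_equal(cl$n_neg, 0)
})

test_that("negation parity is the negator count modulo two", {
  expect_equal(negation_parity(0), 0L)
  expect_equal(negation_parity(1), 1L)
  expect_equal(negation_parity(2), 0L)
  expect_equal(negation_parity(3), 1L)
  expect_equal(negation_parity(list(n_neg = 5)), 1L)
})

test_that("shifter weights follow the amplifier/de-amplifier/adversative rules", {
  mk <- function(n_neg = 0, n_amp = 0, n_deamp = 0, n_ac = 0) {
    list(n_neg = n_neg, n_amp = n_amp, n_deamp = n_deamp, n_ac = n_ac)
  }
  w <- shifter_weights(mk(), lex)
  expect_equal(unlist(w), c(w_amp = 0, w_deamp = 0, w_ac = 1))
  expect_equal(shifter_weights(mk(n_amp = 1), lex)$w_amp, 0.8)
  # a negated amplifier becomes an attenuator
  w <- shifter_weights(mk(n_neg = 1, n_amp = 1), lex)
  expect_equal(w$w_amp, 0)
  expect_equal(w$w_deamp, -0.8)
  # attenuation floors at -1
  expect_equal(shifter_weights(mk(n_deamp = 2), lex)$w_deamp, -1)
  expect_equal(shifter_weights(mk(n_ac = 2), lex)$w_ac, 1.5)
  # adversative weighting can be disabled
  cfg <- eva_config(use_adversative = FALSE)
  expect_equal(shifter_weights(mk(n_ac = 2), lex, cfg)$w_ac, 1)
})

test_that("cluster scores flip or nullify under negation", {
  expect_equal(cluster_score(1, 0), 1)
  expect_equal(cluster_score(1, 1), -1)
  expect_equal(cluster_score(1, 1, negation_mode = "nullify"), 0)
  expect_equal(cluster_score(0.5, 0, w_amp = 0.8), 0.9)
  expect_equal(cluster_score(-0.5, 0, w_deamp = -1), 0)
})

test_that("sentence scores normalize the cluster sum by sentence length", {
  expect_equal(sentence_score("we met in the lab", lex)$delta, 0)
  expect_equal(sentence_score("", lex)$delta, 0)
  # one cluster C' = 0.5 over 4 tokens
  expect_equal(sentence_score("a good day here", lex)$delta, 0.125)
  cfg <- eva_config(denominator_mode = "sqrt")
  expect_equal(sentence_score("a good day here", lex, cfg)$delta, 0.25)
})

test_that("document scoring preserves order, length and determinism", {
  doc <- as_document("d", "Good start. We met today. Bad end.")
  s <- score_document(doc, lex)
  expect_length(s, 3)
  expect_true(s[1] > 0)
  expect_equal(as.numeric(s)[2], 0)
  expect_true(s[3] < 0)
  expect_identical(s, score_document(doc, lex))
  expect_length(score_document(as_document("e", ""), lex), 0)
})

test_that("scorer matches the brute-force cluster-equation oracle on random sentences", {
  vocab <- oracle_vocab(lex)
  set.seed(42)
  for (trial in 1:400) {
    n <- sample(1:10, 1)
    norms <- random_norms(n, vocab)
    mode <- sample(c("flip", "nullify"), 1)
    denom <- sample(c("linear", "sqrt"), 1)
    cfg <- eva_config(negation_mode = mode, denominator_mode = denom)
    sent <- new_sent <- paste(norms, collapse = " ")
    got <- sentence_score(sent, lex, cfg)$delta
    want <- oracle_sentence_score(norms, lex, negation_mode = mode,
                                  denominator_mode = denom)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("negating the lexicon negates every score; scaling valences scales them", {
  vocab <- oracle_vocab(lex)
  neg_lex <- lexicon(-lex$valence, lex$negators, lex$amplifiers,
                     lex$deamplifiers, character(0))
  base_lex <- lexicon(lex$valence, lex$negators, lex$amplifiers,
                      lex$deamplifiers, character(0))
  half_lex <- lexicon(lex$valence / 2, lex$negators, lex$amplifiers,
                      lex$deamplifiers, lex$adversatives)
  set.seed(7)
  for (trial in 1:100) {
    sent <- paste(random_norms(sample(2:12, 1), vocab), collapse = " ")
    d <- sentence_score(sent, base_lex)$delta
    expect_equal(sentence_score(sent, neg_lex)$delta, -d, tolerance = 1e-12)
    d_full <- sentence_score(sent, lex)$delta
    expect_equal(sentence_score(sent, half_lex)$delta, d_full / 2,
                 tolerance = 1e-12)
  }
})

test_that("cluster scores stay within the amplification bound", {
  vocab <- oracle_vocab(lex)
  bound <- (1 + 0.8 * 7) * (1 + 0.25 * 7)
  set.seed(11)
  for (trial in 1:200) {
    sent <- paste(random_norms(sample(1:8, 1), vocab), collapse = " ")
    cs <- sentence_score(sent, lex)$cluster_scores
    expect_true(all(abs(cs) <= bound + 1e-12))
  }
})
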