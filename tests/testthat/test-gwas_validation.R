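make_windows <- function(chr, anchor, half = 500000, id = NULL) {
  data.frame(mqtl_id = id %||% sprintf("MQTL%d.%d", chr, seq_along(anchor)),
             chr = chr, start_bp = pmax(1, anchor - half),
             end_bp = anchor + half, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("MQTL windows are the anchor +/- 0.5 Mbp, clipped at the edges", {
  mq <- data.frame(mqtl_id = c("MQTL1.1", "MQTL1.2"), chr = 1L,
                   peak_cm = c(20, 1), ci_low_cm = c(19, 0.5),
                   ci_high_cm = c(21, 1.5), sd_cm = 0.5,
                   n_members = 1L, member_ids = c("q1", "q2"))
  mem <- data.frame(qtl_id = c("q1", "q2"), component = 1:2,
                    membership = c(0.9, 0.95),
                    mqtl_id = c("MQTL1.1", "MQTL1.2"))
  qt <- rbind(make_qtl(qtl_id = "q1", marker_left = "MA",
                       marker_right = "MB"),
              make_qtl(qtl_id = "q2", marker_left = "MC",
                       marker_right = "MD"))
  anchors <- data.frame(marker = c("MA", "MB", "MC"), chr = 1L,
                        position_bp = c(5000000, 5600000, 200000))
  w <- anchor_mqtls(mq, mem, qt, anchors,
                    consensus = data.frame(chr = 1L,
                                           marker = c("MA", "MB", "MC"),
                                           position_cm = c(19.8, 22, 1),
                                           n_maps = 1L))
  # MA is closest to the 20 cM peak -> window 4.5-5.5 Mb
  expect_equal(w$start_bp[w$mqtl_id == "MQTL1.1"], 4500000)
  expect_equal(w$end_bp[w$mqtl_id == "MQTL1.1"], 5500000)
  # left clipping at 1
  expect_equal(w$start_bp[w$mqtl_id == "MQTL1.2"], 1)
  expect_equal(w$end_bp[w$mqtl_id == "MQTL1.2"], 700000)
})

test_that("MQTLs without an anchorable marker are excluded with a warning", {
  mq <- data.frame(mqtl_id = "MQTL1.1", chr = 1L, peak_cm = 20,
                   ci_low_cm = 19, ci_high_cm = 21, sd_cm = 0.5,
                   n_members = 1L, member_ids = "q1")
  mem <- data.frame(qtl_id = "q1", component = 1L, membership = 0.9,
                    mqtl_id = "MQTL1.1")
  qt <- make_qtl(qtl_id = "q1", marker_left = "MX", marker_right = "MY")
  anchors <- data.frame(marker = "MZ", chr = 1L, position_bp = 1e6)
  expect_warning(w <- anchor_mqtls(mq, mem, qt, anchors), "no anchorable")
  expect_equal(nrow(w), 0L)
  expect_equal(attr(w, "unanchored"), "MQTL1.1")
})

test_that("co-localization boundaries and thresholds are inclusive", {
  w <- make_windows(1L, 5000000)
  mtas <- data.frame(
    snp_id = c("edge_lo", "edge_hi", "in_weak", "out", "in_strong"),
    chr = 1L,
    position_bp = c(4500000, 5500000, 5000000, 5500001, 4900000),
    neg_log10_p = c(5.0, 6.0, 4.99, 9.0, 7.2),
    trait = "t", panel_id = "p")
  res <- colocalize(w, mtas, threshold = 5.0)
  expect_setequal(res$hits$snp_id, c("edge_lo", "edge_hi", "in_strong"))
  expect_equal(res$summary$n_mtas, 3L)
  expect_true(res$summary$validated)
})

test_that("co-localization equals the brute-force double loop", {
  set.seed(77)
  n_w <- 300; n_s <- 1500
  w <- data.frame(mqtl_id = sprintf("W%03d", seq_len(n_w)),
                  chr = sample(1:5, n_w, replace = TRUE),
                  start_bp = sample(1:5e6, n_w, replace = TRUE))
  w$end_bp <- w$start_bp + sample(1e5:1e6, n_w, replace = TRUE)
  mtas <- data.frame(snp_id = sprintf("S%04d", seq_len(n_s)),
                     chr = sample(1:5, n_s, replace = TRUE),
                     position_bp = sample(1:6e6, n_s, replace = TRUE),
                     neg_log10_p = round(runif(n_s, 0, 10), 2),
                     trait = "t", panel_id = "p")
  # plant exact boundary/threshold coincidences
  mtas$position_bp[1:5] <- w$start_bp[1:5]; mtas$chr[1:5] <- w$chr[1:5]
  mtas$neg_log10_p[1:10] <- 5.0
  res <- colocalize(w, mtas, threshold = 5.0)
  expect_equal(res$summary$n_mtas,
               oracle_colocalize_counts(w, mtas, 5.0))
})

test_that("the validated fraction never increases with the threshold", {
  set.seed(8)
  w <- make_windows(1L, seq(1e6, 2e7, by = 1e6))
  mtas <- data.frame(snp_id = sprintf("S%d", 1:400), chr = 1L,
                     position_bp = sample(1:2.1e7, 400),
                     neg_log10_p = runif(400, 0, 10),
                     trait = "t", panel_id = "p")
  fr <- vapply(c(2, 4, 5, 6, 8), function(th)
    colocalize(w, mtas, threshold = th)$validated_fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("simulated MTA panels validate exactly the planted windows", {
  cfg <- sim_config(seed = 13, n_chromosomes = 2,
                    mta_planted_fraction = 0.5)
  tw <- true_windows(cfg)
  sim <- simulate_mtas(cfg, tw)
  w <- data.frame(mqtl_id = tw$locus_id, chr = tw$chr,
                  start_bp = tw$start_bp, end_bp = tw$end_bp)
  res <- colocalize(w, sim$mtas, threshold = 5.0)
  expect_setequal(res$summary$mqtl_id[res$summary$validated], sim$truth)
  expect_equal(length(sim$truth), round(0.5 * nrow(tw)))
  # extremes
  cfg1 <- sim_config(seed = 13, n_chromosomes = 2, mta_planted_fraction = 1)
  s1 <- simulate_mtas(cfg1, tw)
  expect_equal(sum(colocalize(w, s1$mtas)$summary$validated), nrow(tw))
  cfg0 <- sim_config(seed = 13, n_chromosomes = 2, mta_planted_fraction = 0)
  s0 <- simulate_mtas(cfg0, tw)
  expect_equal(sum(colocalize(w, s0$mtas)$summary$validated), 0L)
})
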