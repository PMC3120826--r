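# Ideal observer: evidence region geometry, transition models, LLR decisions.

test_that("area 3 matches brute-force enumeration on arbitrary masks", {
  set.seed(42)
  for (dir_d in c(0, 90, 180, 270)) {
    for (d in 0:2) {
      mask <- matrix(runif(64) < 0.6, 8, 8)
      a3 <- area3(mask, d, dir_d)
      # independent enumeration: p is evidence iff p in mask and p + d*u
      # leaves the mask (content has no destination in the next frame)
      th <- dir_d * pi / 180
      vr <- -round(d * sin(th))
      vc <- round(d * cos(th))
      ref <- matrix(FALSE, 8, 8)
      for (i in 1:8) {
        for (j in 1:8) {
          if (!mask[i, j]) next
          di <- i + vr
          dj <- j + vc
          outside <- di < 1 || di > 8 || dj < 1 || dj > 8 || !mask[di, dj]
          ref[i, j] <- d > 0 && outside
        }
      }
      expect_identical(a3$mask, ref)
    }
  }
})

test_that("area 3 is a displacement-wide band on the leading edge", {
  mask <- make_center_mask(c(96L, 96L), 2.4, 25, 1, outline_amplitude = 0)
  a3 <- area3(mask, 2, 90)  # upward motion
  expect_true(all(which(a3$mask, arr.ind = TRUE)[, 1] < 48))  # top half only
  # every evidence pixel is within displacement_px of the mask boundary
  outside_above <- !rbind(matrix(FALSE, 2, 96), mask[1:94, ])
  expect_true(all(a3$mask <= (mask & outside_above[1:96, ])))
  # |area3| ~ displacement x projected boundary extent
  cols_hit <- range(which(colSums(mask) > 0))
  extent <- diff(cols_hit) + 1
  expect_lt(abs(sum(a3$mask) - 2 * extent) / (2 * extent), 0.15)
  # zero displacement -> empty
  expect_false(any(area3(mask, 0, 90)$mask))
})

test_that("transition distributions normalize and reduce correctly", {
  p <- observer_params(switch_prob = 0, dot_density = 0.5)
  pf <- transition_probs("F", p)
  pn <- transition_probs("N", p)
  expect_equal(rowSums(pf), c(`0` = 1, `1` = 1))
  expect_equal(rowSums(pn), c(`0` = 1, `1` = 1))
  # r = 0 under F at density 0.5: match probability is chance (0.5^2 + 0.5^2)
  match_prob <- 0.5 * pf["0", "0"] + 0.5 * pf["1", "1"]
  expect_equal(match_prob, 0.5)
  # displacement 0: models coincide, LLR forced to 0
  p0 <- observer_params(displacement_px = 0L)
  expect_identical(transition_probs("F", p0), transition_probs("N", p0))
  f <- matrix(runif(16), 4, 4)
  expect_equal(llr(f, matrix(runif(16), 4, 4),
                   matrix(TRUE, 4, 4), p0), 0)
})

test_that("per-pair LLR is antisymmetric in the model labels and finite", {
  set.seed(7)
  p <- observer_params(switch_prob = 0.1)
  f1 <- matrix(rbinom(400, 1, 0.5), 20, 20)
  f2 <- matrix(rbinom(400, 1, 0.5), 20, 20)
  mask <- matrix(runif(400) < 0.3, 20, 20)
  val <- llr(f1, f2, mask, p)
  expect_true(is.finite(val))
  # recompute with the labels swapped via the exported transition kernels
  x0 <- f1[mask] > 0.5
  x1 <- f2[mask] > 0.5
  lut_swapped <- log(pmax(transition_probs("N", p), 1e-12)) -
    log(pmax(transition_probs("F", p), 1e-12))
  expect_equal(-sum(lut_swapped[cbind(x0 + 1, x1 + 1)]), val)
  # degenerate r = 0 stays finite through the probability floor
  expect_true(is.finite(llr(f1, f2, mask, observer_params(switch_prob = 0))))
  # empty evidence -> 0 with a notice
  expect_message(v0 <- llr(f1, f2, mask & FALSE, p), "empty evidence")
  expect_identical(v0, 0)
})

test_that("decisions recover the generating model", {
  sp <- small_spec(duration_s = 1, rng_seed = 21)
  tr <- decide_depth_order(generate_sequence(sp))
  expect_identical(tr$decision, "F")
  expect_identical(tr$cumulative, cumsum(tr$per_pair))

  # explicit near-surface generator -> N
  trn <- decide_depth_order(generate_near_model_sequence(sp, 0.1),
                            params_from_spec(sp))
  expect_identical(trn$decision, "N")

  # mean per-pair LLR signs (Monte-Carlo over 500+ pairs)
  expect_gt(mean(tr$per_pair), 0)
  expect_lt(mean(trn$per_pair), 0)

  # zero-speed stimulus -> no evidence, never a coin flip
  tr0 <- decide_depth_order(generate_sequence(
    small_spec(center_speed_deg_per_s = 0)))
  expect_identical(tr0$decision, "no_evidence")
})

test_that("the LLR depends on center pixels only", {
  sp <- small_spec(rng_seed = 13)
  sq <- generate_sequence(sp)
  tr <- decide_depth_order(sq)

  # same center stream, different surround coherence: bit-identical evidence
  sp2 <- small_spec(rng_seed = 13, surround_temporal_coherence = 0.5)
  tr2 <- decide_depth_order(generate_sequence(sp2))
  expect_identical(tr$cumulative, tr2$cumulative)
  expect_identical(tr$decision, tr2$decision)

  # perturbing every surround pixel leaves the trace bit-identical
  pert <- sq
  sidx <- which(pert$surround_mask)
  set.seed(99)
  for (t in seq_len(dim(pert$frames)[3])) {
    fr <- pert$frames[, , t]
    fr[sidx] <- runif(length(sidx))
    pert$frames[, , t] <- fr
  }
  expect_identical(decide_depth_order(pert)$cumulative, tr$cumulative)
})

test_that("evidence strength is flat across surround flicker", {
  sp <- small_spec(duration_s = 0.4, rng_seed = 31)
  tab <- llr_flicker_invariance(sp, coherences = c(0.5, 0.75, 1), n_reps = 4)
  expect_false(attr(tab, "violation"))
  # shared center streams make the means exactly equal, not merely close
  expect_equal(tab$mean_abs_llr, rep(tab$mean_abs_llr[1], 3))
  expect_error(llr_flicker_invariance(sp, coherences = 1), "2 coherence")
  expect_error(llr_flicker_invariance(sp, n_reps = 1), "n_reps")
})

test_that("transition models match Monte-Carlo frequencies from the generators", {
  # moderate-size oracle (the full million-draw check runs with the
  # acceptance suite): empirical conditionals from the two generators
  count_transitions <- function(sq, mask) {
    counts <- matrix(0, 2, 2)
    T_ <- dim(sq$frames)[3]
    prev <- sq$frames[, , 1][mask] > 0.5
    for (t in 2:T_) {
      cur <- sq$frames[, , t][mask] > 0.5
      counts <- counts + table(factor(prev, c(FALSE, TRUE)),
                               factor(cur, c(FALSE, TRUE)))
      prev <- cur
    }
    counts
  }
  sp <- small_spec(duration_s = 1, rng_seed = 55)
  sq <- generate_sequence(sp)
  a3 <- area3(sq$center_mask, 2, 90)
  cf <- count_transitions(sq, a3$mask)
  emp_f <- cf / rowSums(cf)
  expect_lt(max(abs(emp_f - transition_probs("F", params_from_spec(sp)))),
            0.03)

  sqn <- generate_near_model_sequence(sp, switch_prob = 0.1)
  cn <- count_transitions(sqn, a3$mask)
  emp_n <- cn / rowSums(cn)
  expect_lt(max(abs(emp_n - transition_probs("N", params_from_spec(sp)))),
            0.03)
})
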