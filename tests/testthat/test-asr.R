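# Mk-model machinery: transition matrices, pruning likelihood, marginal
# reconstruction, rate fitting, character utilities.

test_that("ER transition matrices match the closed form and an expm oracle", {
  m <- mk_model(3, "ER", rate = 0.4)
  expect_equal(mk_transition_matrix(m, 0), diag(3), ignore_attr = TRUE)
  # stationary limit
  expect_equal(unname(mk_transition_matrix(m, 1e6)), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
  P <- mk_transition_matrix(m, 1.25)
  expect_lt(max(abs(unname(P) - expm_oracle(m$Q * 1.25))), 1e-10)

  withr::with_seed(11, {
    for (i in 1:25) {
      k <- sample(2:5, 1)
      q <- runif(1, 0.01, 3)
      t <- runif(1, 0, 4)
      mod <- mk_model(k, "ER", rate = q)
      P <- unname(mk_transition_matrix(mod, t))
      e <- exp(-k * q * t)
      closed <- matrix((1 - e) / k, k, k)
      diag(closed) <- 1 / k + (1 - 1 / k) * e
      expect_lt(max(abs(P - closed)), 1e-12)
      expect_lt(max(abs(P - expm_oracle(mod$Q * t))), 1e-10)
      expect_equal(rowSums(P), rep(1, k), tolerance = 1e-12)
    }
  })

  expect_error(mk_transition_matrix(m, -1), class = "phyloskim_invalid_input")
})

test_that("ARD transition matrices agree with the expm oracle", {
  withr::with_seed(5, {
    rates <- runif(6, 0.1, 2)
    m <- mk_model(3, "ARD", rates = rates)
    expect_equal(unname(rowSums(m$Q)), rep(0, 3), tolerance = 1e-12)
    for (t in c(0, 0.3, 2)) {
      expect_lt(max(abs(unname(mk_transition_matrix(m, t)) -
                          expm_oracle(m$Q * t))), 1e-8)
    }
  })
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  skip_if_not_installed("phangorn")
  withr::with_seed(21, {
    for (n in 4:6) {
      trees <- all_rooted_trees(n, seed = n)
      pick <- sample(seq_along(trees), 6)
      for (i in pick) {
        tr <- trees[[i]]
        for (k in 2:4) {
          model <- mk_model(k, "ER", rate = runif(1, 0.1, 1.5))
          states <- setNames(sample(model$states, n, TRUE), tr$tip.label)
          oracle <- brute_mk(tr, states, model)
          expect_equal(mk_loglikelihood(tr, states, model), oracle$loglik,
                       tolerance = 1e-10)
          rec <- marginal_states(tr, states, model)
          expect_lt(max(abs(rec$probabilities - oracle$marginals)), 1e-9)
        }
      }
    }
  })
})

test_that("degenerate and symmetric cases behave analytically", {
  # zero branch lengths, all tips in one state: likelihood is the root prior
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  m <- mk_model(3, "ER", rate = 0.7, root_prior = c(0.2, 0.5, 0.3))
  states <- c(a = "B", b = "B", c = "B")
  expect_equal(mk_loglikelihood(tr, states, m), log(0.5), tolerance = 1e-12)

  # two tips on equal branches in different states: swap symmetry and a
  # 50/50 root marginal
  tr2 <- ape::read.tree(text = "(a:1,b:1);")
  m2 <- mk_model(2, "ER", rate = 0.3)
  l1 <- mk_loglikelihood(tr2, c(a = "A", b = "B"), m2)
  l2 <- mk_loglikelihood(tr2, c(a = "B", b = "A"), m2)
  expect_equal(l1, l2, tolerance = 1e-12)
  rec <- marginal_states(tr2, c(a = "A", b = "B"), m2)
  expect_equal(unname(rec$probabilities[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("unknown and polymorphic tips enter as partial likelihoods", {
  withr::with_seed(9, {
    tr <- all_rooted_trees(5, seed = 2)[[10]]
    m <- mk_model(3, "ER", rate = 0.6)
    states <- setNames(c("A", "B", NA, "C", "B"), tr$tip.label)
    oracle <- brute_mk(tr, states, m)
    expect_equal(mk_loglikelihood(tr, states, m), oracle$loglik, tolerance = 1e-10)

    # polymorphic tip: indicator row with two allowed states
    ind <- matrix(0, 5, 3, dimnames = list(tr$tip.label, m$states))
    ind[cbind(1:5, c(1, 2, 1, 3, 2))] <- 1
    ind[3, ] <- c(1, 1, 0)
    oracle2 <- brute_mk(tr, ind, m)
    expect_equal(mk_loglikelihood(tr, ind, m), oracle2$loglik, tolerance = 1e-10)
  })

  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  m <- mk_model(2, "ER", rate = 0.5)
  expect_error(mk_loglikelihood(tr, c(a = "A", b = "B"), m),
               "c", class = "phyloskim_missing_taxon")
})

test_that("polytomies are accepted directly by the pruning algorithm", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  m <- mk_model(2, "ER", rate = 0.4)
  states <- c(a = "A", b = "A", c = "B", d = "A")
  oracle <- brute_mk(star, states, m)
  expect_equal(mk_loglikelihood(star, states, m), oracle$loglik,
               tolerance = 1e-10)
  rec <- marginal_states(star, states, m)
  expect_equal(unname(rowSums(rec$probabilities)), 1, tolerance = 1e-12)
})

test_that("node marginals are invariant to the root position under a reversible model", {
  withr::with_seed(31, {
    tr <- ape::rtree(6)
    m <- mk_model(3, "ER", rate = 0.5)
    states <- setNames(sample(m$states, 6, TRUE), tr$tip.label)
    rec <- marginal_states(tr, states, m)
    n_tip <- 6
    tested <- 0
    for (node in (n_tip + 2):(n_tip + tr$Nnode)) {
      # re-root so `node` becomes the new root; under ER with a uniform
      # prior its marginal must not change
      re <- ape::root(tr, node = node, resolve.root = FALSE)
      rec2 <- marginal_states(re, states, m)
      expect_equal(
        unname(rec$probabilities[as.character(node), ]),
        unname(rec2$probabilities[as.character(n_tip + 1), ]),
        tolerance = 1e-9
      )
      tested <- tested + 1
    }
    expect_gt(tested, 0)
  })
})

test_that("consensus tips give a consensus reconstruction", {
  tr <- simulate_tree(8, seed = 2)
  m <- mk_model(3, "ER", rate = 1e-3)
  states <- setNames(rep("A", 8), tr$tip.label)
  rec <- marginal_states(tr, states, m)
  expect_true(all(rec$map_state == "A"))
  expect_equal(unname(rowSums(rec$probabilities)),
               rep(1, nrow(rec$probabilities)), tolerance = 1e-9)
})

test_that("rate fitting honours the q*t scaling and boundary conventions", {
  withr::with_seed(41, {
    tr <- simulate_tree(30, seed = 14)
    ch <- simulate_character(tr, mk_model(2, "ER", rate = 0.8), seed = 15)
    fit1 <- fit_mk_rate(tr, ch$tip_states)
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 2
    fit2 <- fit_mk_rate(tr2, ch$tip_states)
    expect_equal(fit2$model$rate, fit1$model$rate / 2, tolerance = 1e-4)
    expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
    expect_true(fit1$convergence)

    # identical tips: estimate pinned to the lower bound with a warning
    flat <- setNames(rep("A", 30), tr$tip.label)
    expect_warning(
      fit0 <- fit_mk_rate(tr, flat, state_labels = c("A", "B")),
      class = "phyloskim_boundary"
    )
    expect_equal(fit0$model$rate, 1e-8)
    expect_true(fit0$boundary)
  })
})

test_that("fitted ER rates agree with an independent ML implementation", {
  withr::with_seed(51, {
    tr <- simulate_tree(40, seed = 16)
    ch <- simulate_character(tr, mk_model(3, "ER", rate = 0.6), seed = 17)
    fit <- fit_mk_rate(tr, ch$tip_states)
    ace_fit <- ape::ace(ch$tip_states[tr$tip.label], tr,
                        type = "discrete", model = "ER")
    expect_equal(fit$model$rate, unname(ace_fit$rates), tolerance = 1e-3)
  })
})

test_that("tidiers expose rates and fit summaries", {
  tr <- simulate_tree(12, seed = 3)
  ch <- simulate_character(tr, mk_model(2, "ER", rate = 0.5), seed = 4)
  fit <- fit_mk_rate(tr, ch$tip_states)
  td <- tidy(fit)
  expect_equal(td$term, "rate")
  expect_equal(td$estimate, fit$model$rate)
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)

  rec <- marginal_states(tr, ch$tip_states, fit$model)
  long <- tidy(rec)
  expect_equal(nrow(long), nrow(rec$probabilities) * fit$model$k)
  sums <- long |> dplyr::group_by(node) |>
    dplyr::summarise(s = sum(probability))
  expect_equal(sums$s, rep(1, nrow(rec$probabilities)), tolerance = 1e-9)
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("leaf measurements discretise at the 225/2025 boundaries", {
  out <- classify_leaf(c(30, 10, 52), c(10, 10, 52))
  expect_equal(out$area, c(225, 75, 2028))
  expect_equal(as.character(out$size_class), c("medium", "small", "large"))
  expect_error(classify_leaf(0, 5), class = "phyloskim_invalid_input")
  expect_error(classify_leaf(5, -1), class = "phyloskim_invalid_input")
})

test_that("state frequencies are proportions over known states", {
  states <- setNames(c(rep("A", 5), rep("B", 3), rep("C", 2)),
                     sprintf("t%02d", 1:10))
  freq <- summarize_state_frequencies(states)
  expect_equal(freq$proportion[freq$state == "A"], 0.5)
  expect_equal(freq$proportion[freq$state == "B"], 0.3)
  expect_equal(freq$proportion[freq$state == "C"], 0.2)
  expect_equal(sum(freq$proportion), 1, tolerance = 1e-12)

  one <- summarize_state_frequencies(setNames("A", "t1"))
  expect_equal(one$proportion, 1)

  # unknowns drop out of the denominator; subsets are honoured
  mixed <- setNames(c("A", NA, "B", "A"), c("t1", "t2", "t3", "t4"))
  f2 <- summarize_state_frequencies(mixed, taxa = c("t1", "t2", "t3"))
  expect_equal(sum(f2$n), 2)
  expect_error(summarize_state_frequencies(mixed, taxa = character(0)),
               class = "phyloskim_invalid_input")
})

test_that("character matrices validate against the six-character scheme", {
  cm <- character_matrix(tibble::tibble(
    taxon = c("t1", "t1", "t2"),
    character = c("capitulum_type", "life_form", "capitulum_type"),
    state = c("type1", "shrub", "type4")
  ))
  expect_s3_class(cm, "character_matrix")
  v <- character_states(cm, "capitulum_type")
  expect_equal(unname(v[c("t1", "t2")]), c("type1", "type4"))

  expect_error(character_matrix(tibble::tibble(
    taxon = "t1", character = "capitulum_type", state = "type9"
  )), class = "phyloskim_invalid_input")
  expect_error(character_matrix(tibble::tibble(
    taxon = "t1", character = "petal_count", state = "5"
  )), class = "phyloskim_invalid_input")
  expect_equal(nrow(morphological_characters()), 6)
})
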