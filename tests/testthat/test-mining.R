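basket <- function(...) {
  tx <- list(...)
  names(tx) <- paste0("s", seq_along(tx))
  structure(list(transactions = tx, n_transactions = length(tx)),
            class = "transaction_db")
}

uniform_wv <- function(items, value) {
  genes <- sort(unique(item_genes(items)))
  matrix(value, length(genes), length(genes), dimnames = list(genes, genes))
}

test_that("item frequencies count, filter and order correctly", {
  db <- basket(c("a", "b"), c("a"), c("b", "c"), c("a", "c"), character(0),
               c("a"), c("c"), c("a"), c("b"), c("a"))
  supp <- item_frequencies(db)
  expect_equal(supp[["a"]], 0.6)
  expect_equal(supp[["b"]], 0.3)
  expect_equal(supp[["c"]], 0.3)
  expect_identical(names(supp), c("a", "b", "c"))  # desc support, lex ties
  expect_identical(names(item_frequencies(db, min_support = 0.5)), "a")
  # brute-force scan oracle on a random DB
  withr::with_seed(5, {
    db2 <- random_db(8, 8)
    supp2 <- item_frequencies(db2)
    for (it in names(supp2))
      expect_equal(supp2[[it]], oracle_support(db2$transactions, it))
  })
})

test_that("FP-growth reproduces the worked small example exactly", {
  db <- basket(c("a", "b"), c("a", "b"), c("a"))
  out <- mine_frequent(db, min_support = 0.6)
  got <- set_keys(out$items, out$support)
  want <- set_keys(list("a", "b", c("a", "b")), c(1, 2 / 3, 2 / 3))
  expect_identical(got, want)
  # no universal item at min support 1
  expect_equal(nrow(mine_frequent(db, min_support = 1)), 1L)  # only {a}
  expect_equal(nrow(mine_frequent(basket(c("a"), c("b")), min_support = 1)), 0L)
})

test_that("FP-growth equals powerset enumeration on random databases", {
  withr::with_seed(17, {
    for (i in 1:40) {
      db <- random_db(sample(3:8, 1), sample(4:15, 1), p_item = runif(1, 0.2, 0.7))
      ms <- runif(1, 0.05, 0.6)
      maxs <- sample(2:4, 1)
      mined <- mine_frequent(db, ms, max_size = maxs)
      oracle <- oracle_frequent_sets(db$transactions, ms, max_size = maxs)
      expect_identical(
        set_keys(mined$items, mined$support),
        set_keys(lapply(oracle, `[[`, "items"),
                 vapply(oracle, `[[`, numeric(1), "support")))
      # anti-monotonicity on the mined lattice
      if (nrow(mined)) {
        supp_of <- stats::setNames(mined$support,
                                   vapply(mined$items, paste, "", collapse = ","))
        for (j in which(mined$size > 1)) {
          items <- mined$items[[j]]
          for (drop in seq_along(items)) {
            sub <- paste(items[-drop], collapse = ",")
            expect_gte(supp_of[[sub]], mined$support[j])
          }
        }
      }
    }
  })
})

test_that("absolute-count support threshold is accepted", {
  db <- basket(c("a", "b"), c("a", "b"), c("a"), c("c"))
  frac <- mine_frequent(db, 0.5)
  cnt <- mine_frequent(db, 2, count_based = TRUE)
  expect_identical(set_keys(frac$items, frac$support),
                   set_keys(cnt$items, cnt$support))
})

test_that("dynamic support filter keeps/drops by the per-set threshold", {
  db <- basket(c("a", "b"), c("a", "b"), c("a", "c"), c("b", "c"), c("a"))
  sets <- mine_frequent(db, 0.2)
  genes <- c("a", "b", "c")
  wv <- matrix(0.25, 3, 3, dimnames = list(genes, genes))
  wv["a", "b"] <- wv["b", "a"] <- 0.35
  kept <- filter_by_dbvs(sets, wv, uvmin_s = 0.25)
  keys <- vapply(kept$items, paste, "", collapse = ",")
  expect_true("a,b" %in% keys)    # support 0.40 >= its threshold 0.35
  expect_false("a,c" %in% keys)   # support 0.20 <  its threshold 0.25
  expect_false("b,c" %in% keys)
  expect_true(all(kept$support >= kept$dbvs - 1e-12))
})

test_that("rule metrics match a direct counting oracle", {
  withr::with_seed(23, {
    for (i in 1:15) {
      db <- random_db(5, 12, p_item = 0.5)
      sets <- mine_frequent(db, 0.2, max_size = 4)
      wv0 <- uniform_wv(unique(unlist(db$transactions)), 0)  # no filtering
      kept <- filter_by_dbvs(sets, wv0, uvmin_s = 0)
      rules <- generate_rules(kept, sets, wv0, wv0, uvmin_c = 1e-9,
                              ud_min_l = 1e-9, wesd = NULL)
      expect_true(all(vapply(seq_len(nrow(rules)), function(j)
        length(intersect(rules$antecedent[[j]], rules$consequent[[j]])) == 0,
        logical(1))))
      for (j in seq_len(min(nrow(rules), 30))) {
        A <- rules$antecedent[[j]]; B <- rules$consequent[[j]]
        sAB <- oracle_support(db$transactions, c(A, B))
        sA <- oracle_support(db$transactions, A)
        sB <- oracle_support(db$transactions, B)
        expect_equal(rules$support[j], sAB)
        expect_equal(rules$confidence[j], sAB / sA)
        expect_equal(rules$lift[j], sAB / sA / sB)
        expect_gte(rules$confidence[j], rules$support[j] - 1e-12)
      }
    }
  })
})

test_that("worked confidence/lift example: {a,b} with supp(a)=0.6, supp(ab)=0.3", {
  db <- basket(c("a", "b"), c("a", "b"), c("a", "b"), c("a"), c("a"), c("a"),
               c("b", "x"), c("b", "x"), character(0), character(0))
  # supp(a)=0.6, supp(b)=0.5, supp(ab)=0.3
  sets <- mine_frequent(db, 0.1)
  wv0 <- uniform_wv(c("a", "b", "x"), 0)
  rules <- generate_rules(filter_by_dbvs(sets, wv0, 0), sets, wv0, wv0,
                          uvmin_c = 1e-9, ud_min_l = 1e-9)
  r <- rules[rules$rule == "a -> b", ]
  expect_equal(r$confidence, 0.5)
  expect_equal(r$lift, 1.0)  # confidence 0.5 / supp(b) 0.5: independence
})

test_that("multi-item consequents are enumerated (all bipartitions)", {
  db <- basket(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c"))
  sets <- mine_frequent(db, 0.5)
  wv0 <- uniform_wv(c("a", "b", "c"), 0)
  rules <- generate_rules(filter_by_dbvs(sets, wv0, 0), sets, wv0, wv0,
                          uvmin_c = 1e-9, ud_min_l = 1e-9)
  three <- rules[vapply(rules$antecedent, length, 1L) +
                 vapply(rules$consequent, length, 1L) == 3L, ]
  expect_equal(nrow(three), 6L)  # 2^3 - 2 bipartitions of {a,b,c}
  expect_true("a -> b, c" %in% three$rule)
})

test_that("degenerate distances reduce dynamic mining to static thresholds", {
  withr::with_seed(31, {
    for (i in 1:10) {
      db <- random_db(6, 10, p_item = 0.5)
      items <- unique(unlist(db$transactions))
      if (length(items) < 2) next
      genes <- sort(unique(item_genes(items)))
      wesd <- matrix(1, length(genes), length(genes),
                     dimnames = list(genes, genes))
      diag(wesd) <- 0
      ud_s <- 0.3; ud_c <- 0.6; ud_l <- 1
      expect_warning(wv_s <- wv_threshold_matrix(wesd, ud_s), "MAD = 0")
      expect_warning(wv_c <- wv_threshold_matrix(wesd, ud_c), "MAD = 0")
      expect_warning(wv_l <- wv_threshold_matrix(wesd, ud_l), "MAD = 0")
      sets <- mine_frequent(db, ud_s)
      kept <- filter_by_dbvs(sets, wv_s, ud_s)
      expect_equal(nrow(kept), nrow(sets))  # dbvs == ud_s everywhere
      rules <- generate_rules(kept, sets, wv_c, wv_l, uvmin_c = ud_c,
                              ud_min_l = ud_l, wesd = wesd)
      # static oracle: enumerate frequent sets and bipartitions directly
      oracle <- oracle_frequent_sets(db$transactions, ud_s, max_size = 4)
      static <- character(0)
      for (os in oracle) {
        set <- os$items
        if (length(set) < 2) next
        for (mask in seq_len(2^length(set) - 2)) {
          sel <- as.logical(bitwAnd(mask, 2^(seq_along(set) - 1)))
          A <- set[sel]; B <- set[!sel]
          conf <- os$support / oracle_support(db$transactions, A)
          lift <- conf / oracle_support(db$transactions, B)
          if (conf >= ud_c - 1e-12 && lift >= ud_l - 1e-12)
            static <- c(static, rule_str <- paste(
              paste(sort(A), collapse = ", "), "->",
              paste(sort(B), collapse = ", ")))
        }
      }
      expect_setequal(rules$rule, static)
    }
  })
})

test_that("planted-module rules are mined from synthetic data", {
  hits <- vapply(1:20, function(seed) {
    sim <- generate_paired_omics(synth_config(
      n_genes = 30, n_modules = 2, module_size = 3, effect_size = 4,
      seed = seed))
    res <- suppressWarnings(run_pipeline(
      pipeline_config(seed = seed, log_level = "quiet"),
      data = list(expr = sim$omics$expression, meth = sim$omics$methylation,
                  labels = sim$omics$labels, ppi = sim$ppi,
                  biosim = sim$biosim)))
    if (is.null(res$rules) || nrow(res$rules) == 0) return(FALSE)
    rule_genes <- lapply(seq_len(nrow(res$rules)), function(j)
      unique(item_genes(c(res$rules$antecedent[[j]], res$rules$consequent[[j]]))))
    any(vapply(rule_genes, function(g)
      any(vapply(sim$truth$planted_modules, function(mod) all(g %in% mod),
                 logical(1))), logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
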