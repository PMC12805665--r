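# accuracy: site accuracy, RMSE, criterion loss.

# NowFit built by hand from canonical IDs (no fitting involved)
fit_of <- function(windowSize, ids, L = windowSize * length(ids)) {
  n <- length(ids)
  stats <- S4Vectors::DataFrame(
    lnl = rep(-1, n), k = rep(5L, n), n_taxa = rep(4L, n),
    n_unique = rep(4L, n), n_patterns = rep(1L, n), canonical = ids,
    newick = rep("(a:1,b:1,(c:1,d:1):1);", n),
    mean_support = rep(NA_real_, n), analyzable = !is.na(ids))
  methods::new("NowFit", windowSize = as.integer(windowSize),
               intervals = IRanges::IRanges(
                 start = (seq_len(n) - 1L) * windowSize + 1L,
                 width = windowSize),
               stats = stats, blmin = 1 / windowSize,
               nSites = windowSize * sum(!is.na(ids)))
}

truth_ids <- function(starts, ends, ids, total = max(ends)) {
  methods::new("TruthMap",
               intervals = IRanges::IRanges(starts + 1L, ends),
               newick = rep("(a:1,b:1,(c:1,d:1):1);", length(ids)),
               topology = ids, totalLength = total, seed = 1L)
}

test_that("site accuracy spans its degenerate anchors", {
  truth <- truth_ids(c(0, 500), c(500, 1000), c("T1", "T2"))
  expect_equal(siteAccuracy(truth, fit_of(500, c("T1", "T2"))), 100)
  expect_equal(siteAccuracy(truth, fit_of(1000, "T1")), 50)
  expect_equal(siteAccuracy(truth, fit_of(500, c("T3", "T4"))), 0)
})

test_that("dropped remainders count against plain runs but not analyzed-only scoring", {
  truth <- truth_ids(0, 1000, "T1")
  fit <- fit_of(300, c("T1", "T1", "T1"), L = 1000)  # 100-site remainder
  expect_equal(siteAccuracy(truth, fit, "total"), 90)
  expect_equal(siteAccuracy(truth, fit, "analyzed"), 100)
  # a filtered (unanalyzable) window is excluded under "analyzed"
  fit2 <- fit_of(300, c("T1", NA, "T1"), L = 1000)
  expect_equal(siteAccuracy(truth, fit2, "total"), 60)
  expect_equal(siteAccuracy(truth, fit2, "analyzed"), 100)
})

test_that("length mismatches are rejected", {
  truth <- truth_ids(0, 600, "T1")
  expect_error(siteAccuracy(truth, fit_of(500, c("T1", "T2"))), "beyond")
})

test_that("interval sweep equals the naive per-site loop exactly", {
  set.seed(13)
  for (rep in 1:5) {
    L <- 3000
    bk <- sort(sample(seq(50, L - 50), 6))
    starts <- c(0, bk)
    ends <- c(bk, L)
    ids <- paste0("T", sample(1:3, length(starts), replace = TRUE))
    truth <- truth_ids(starts, ends, ids, total = L)
    ws <- sample(c(100, 250, 400), 1)
    n <- floor(L / ws)
    fids <- paste0("T", sample(1:3, n, replace = TRUE))
    fids[sample(n, 2)] <- NA
    fit <- fit_of(ws, fids, L = L)
    expect_equal(siteAccuracy(truth, fit, "total"),
                 naive_site_accuracy(truth, fit, "total"))
    expect_equal(siteAccuracy(truth, fit, "analyzed"),
                 naive_site_accuracy(truth, fit, "analyzed"))
  }
})

test_that("RMSE reproduces its worked values over the topology union", {
  expect_equal(topologyRmse(c(T1 = 0.5, T2 = 0.5), c(T1 = 0.5, T2 = 0.5)), 0)
  expect_equal(topologyRmse(c(T1 = 1), c(T2 = 1)), 1)  # sqrt((1+1)/2)
  expect_equal(topologyRmse(c(T1 = 0.5, T2 = 0.3, T3 = 0.2),
                            c(T1 = 0.4, T2 = 0.4, T3 = 0.2)),
               sqrt(0.02 / 3))
  expect_equal(topologyRmse(c(T1 = 0.5, T2 = 0.3, T3 = 0.2),
                            c(T1 = 0.4, T2 = 0.4, T3 = 0.2)), 0.08165,
               tolerance = 1e-4)
  expect_error(topologyRmse(setNames(numeric(), character()),
                            setNames(numeric(), character())), "empty")
})

test_that("criterion loss compares against the grid optimum", {
  reports <- data.frame(size = c(1000, 2000), site_accuracy = c(80, 90),
                        rmse = c(0.2, 0.1))
  summaries <- data.frame(size = c(1000, 2000), AIC = c(1, 2),
                          BIC = c(2, 1))
  la <- criterionLoss(reports, summaries, "AIC")   # picks 1000
  expect_equal(la$site_accuracy_loss, 10)
  expect_equal(la$rmse_gain, 0.1)
  lb <- criterionLoss(reports, summaries, "BIC")   # picks the best size
  expect_equal(lb$site_accuracy_loss, 0)
  expect_equal(lb$rmse_gain, 0)
  expect_error(criterionLoss(reports,
                             data.frame(size = c(1000, 4000), AIC = 1:2),
                             "AIC"), "grids")
})

test_that("observed weights normalize and match window proportions", {
  fit <- fit_of(100, c("T1", "T1", "T2", NA))
  w <- observedTopologyWeights(fit)
  expect_equal(sum(w), 1)
  expect_equal(unname(w["T1"]), 2 / 3)
  expect_equal(observedTopologyWeights(fit, "window"), w)
})
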