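test_that("chao1 matches its closed form in both variants", {
    expect_equal(richness(chao1(c(3, 3, 3))), 3)          # no singletons
    expect_equal(richness(chao1(c(1, 1, 2, 3))), 4.5)     # 4 + 2*1/4
    expect_equal(richness(chao1(c(1))), 1)                # F1(F1-1) = 0
    # classic variant: F1^2/(2 F2), falling back when F2 = 0
    expect_equal(richness(chao1(c(1, 1, 2, 3), variant = "classic")),
        4 + 4 / 2)
    expect_equal(richness(chao1(c(1, 1, 3), variant = "classic")),
        3 + 2 * 1 / 2)   # F2 = 0: bias-corrected fallback
    expect_error(chao1(list(sObs = 0, fCounts = numeric(), n = 0,
        abundances = numeric())), "empty")
})

test_that("chao1 ignores site structure by design", {
    set.seed(21)
    for (r in 1:20) {
        m <- randomCountMatrix(sample(2:6, 1), sample(5:20, 1))
        pooled <- matrix(colSums(m), 1,
            dimnames = list("all", colnames(m)))
        expect_equal(richness(chao1(AbundanceMatrix(m))),
            richness(chao1(AbundanceMatrix(pooled))))
    }
})

test_that("ace matches the hand-worked example and its edge cases", {
    # S_rare = 4, N_rare = 9, C = 7/9, gamma^2 = 0.5714
    est <- ace(c(1, 1, 2, 5, 12))
    expect_equal(richness(est), 1 + 4 / (7 / 9) + 2 / (7 / 9) * (22 * 4 / (7 / 9) / 72 - 1),
        tolerance = 1e-12)
    expect_equal(richness(est), 7.612245, tolerance = 1e-6)
    # no rare species at all: estimate = S_obs
    expect_equal(richness(ace(c(11, 12, 13))), 3)
    # all rare species singletons: coverage 0, chao1 fallback with warning
    expect_warning(fb <- ace(c(1, 1)), "falling back")
    expect_equal(richness(fb), richness(chao1(c(1, 1))))
})

test_that("chao2 matches its closed form and validates site counts", {
    inc <- list(sObs = 5, nSites = 4, qCounts = c(`1` = 2, `2` = 1, `3` = 2),
        occupancy = c(1, 1, 2, 3, 3))
    expect_equal(richness(chao2(inc)), 5 + (3 / 4) * 2 * 1 / (2 * 2))
    # Q1 = 0: estimate equals observed richness
    m <- AbundanceMatrix(rbind(T1 = c(a = 1, b = 2), T2 = c(a = 3, b = 1)))
    expect_equal(richness(chao2(m)), 2)
    # classic variant drops the small-sample factor
    expect_equal(richness(chao2(inc, variant = "classic")), 5 + 4 / 2)
    expect_error(chao2(list(sObs = 2, nSites = 1,
        qCounts = c(`1` = 2), occupancy = c(1, 1))), "at least 2 sites")
})

test_that("jackknife orders 1 and 2 match their closed forms", {
    inc <- list(sObs = 5, nSites = 4, qCounts = c(`1` = 2, `2` = 1, `3` = 2),
        occupancy = c(1, 1, 2, 3, 3))
    expect_equal(richness(jackknifeRichness(inc, order = 1)), 6.5)
    expect_equal(richness(jackknifeRichness(inc, order = 2)),
        5 + 2 * 5 / 4 - 1 * 4 / 12)
    # Q1 = Q2 = 0: both orders return S_obs
    inc0 <- list(sObs = 3, nSites = 4, qCounts = c(`3` = 1, `4` = 2),
        occupancy = c(3, 4, 4))
    expect_equal(richness(jackknifeRichness(inc0, order = 1)), 3)
    expect_equal(richness(jackknifeRichness(inc0, order = 2)), 3)
    expect_error(jackknifeRichness(list(sObs = 2, nSites = 2,
        qCounts = c(`1` = 2), occupancy = c(1, 1)), order = 2),
        "at least 3 sites")
})

test_that("jack1 equals the brute-force leave-one-site-out jackknife", {
    set.seed(33)
    for (r in 1:50) {
        m <- randomCountMatrix(sample(3:6, 1), sample(5:20, 1))
        pres <- m > 0
        expect_equal(richness(jackknifeRichness(AbundanceMatrix(m))),
            jack1Oracle(pres))
    }
})

test_that("bootstrap matches direct evaluation", {
    # all species everywhere: (1-1)^n = 0
    m <- AbundanceMatrix(rbind(T1 = c(a = 1, b = 2), T2 = c(a = 3, b = 1)))
    expect_equal(richness(bootstrapRichness(m)), 2)
    # one species at 1 of 2 sites
    inc <- list(sObs = 1, nSites = 2, qCounts = c(`1` = 1), occupancy = 1)
    expect_equal(richness(bootstrapRichness(inc)), 1.25)
    # occupancies {1 of 4, 4 of 4}
    inc2 <- list(sObs = 2, nSites = 4, qCounts = c(`1` = 1, `4` = 1),
        occupancy = c(1, 4))
    expect_equal(richness(bootstrapRichness(inc2)), 2 + (3 / 4)^4)
})

test_that("bootstrap is below jack1 when every species is a unique", {
    # per-species: (1 - 1/n)^n < (n-1)/n for n >= 2, so the inequality is a
    # theorem when all occupancies are 1.  (It is NOT true for arbitrary
    # matrices: species at m >= 2 sites add to the bootstrap but not to
    # jack1 -- see the counterexample below.)
    for (n in 2:6) {
        q1 <- 5
        inc <- list(sObs = q1, nSites = n,
            qCounts = stats::setNames(q1, "1"), occupancy = rep(1, q1))
        expect_lt(richness(bootstrapRichness(inc)),
            richness(jackknifeRichness(inc, order = 1)))
    }
    # counterexample: one unique plus many duplicates
    incc <- list(sObs = 21, nSites = 10,
        qCounts = c(`1` = 1, `2` = 20), occupancy = c(1, rep(2, 20)))
    expect_gt(richness(bootstrapRichness(incc)),
        richness(jackknifeRichness(incc, order = 1)))
})

test_that("estimators agree with the vegan reference implementations", {
    set.seed(77)
    for (r in 1:20) {
        m <- randomCountMatrix(sample(3:8, 1), sample(10:30, 1))
        x <- AbundanceMatrix(m)
        # abundance-based: estimateR on the pooled sample
        er <- suppressWarnings(vegan::estimateR(colSums(m)))
        expect_equal(richness(chao1(x)), unname(er["S.chao1"]),
            tolerance = 1e-8)
        if (is.finite(er["S.ACE"]) && !is.nan(er["S.ACE"])) {
            aceEst <- suppressWarnings(ace(x))
            if (is.null(aceEst@inputs$fallback))
                expect_equal(richness(aceEst), unname(er["S.ACE"]),
                    tolerance = 1e-8)
        }
        # incidence-based: specpool on the site-by-species table.  vegan's
        # chao uses the classic Q1^2/(2 Q2) numerator (with the small-sample
        # factor) when Q2 > 0, so validate our occupancy summary by
        # reassembling vegan's convention from it; when Q2 = 0 the two
        # conventions coincide and the estimates must match directly.
        sp <- vegan::specpool(m)
        inc <- incidenceSummary(x)
        q1 <- sum(inc$occupancy == 1); q2 <- sum(inc$occupancy == 2)
        n <- inc$nSites
        veganChao <- inc$sObs + if (q2 > 0) (n - 1) / n * q1^2 / (2 * q2)
            else (n - 1) / n * q1 * (q1 - 1) / 2
        expect_equal(veganChao, sp$chao, tolerance = 1e-8)
        if (q2 == 0)
            expect_equal(richness(chao2(x)), sp$chao, tolerance = 1e-8)
        expect_equal(richness(jackknifeRichness(x, 1)), sp$jack1,
            tolerance = 1e-8)
        expect_equal(richness(jackknifeRichness(x, 2)), sp$jack2,
            tolerance = 1e-8)
        expect_equal(richness(bootstrapRichness(x)), sp$boot,
            tolerance = 1e-8)
    }
})

test_that("every estimator returns at least the observed richness", {
    set.seed(55)
    for (r in 1:30) {
        m <- randomCountMatrix(sample(3:7, 1), sample(8:25, 1))
        x <- AbundanceMatrix(m)
        sObs <- nSpecies(x)
        for (f in list(chao1, function(z) suppressWarnings(ace(z)), chao2,
            function(z) jackknifeRichness(z, 1), bootstrapRichness))
            expect_gte(richness(f(x)), sObs - 1e-9)
    }
})

test_that("Gaussian octave fit recovers noiseless parameters exactly", {
    o <- 0:12
    y <- 10 * exp(-(o - 4)^2 / (2 * 2^2))
    fit <- fitOctaveGaussian(o, y)
    expect_equal(fit$height, 10, tolerance = 1e-6)
    expect_equal(fit$mode, 4, tolerance = 1e-6)
    expect_equal(fit$width, 2, tolerance = 1e-6)
    # veiled richness equals the closed-form Gaussian area
    expect_equal(fit$height * fit$width * sqrt(2 * pi), 10 * 2 * sqrt(2 * pi),
        tolerance = 1e-6)
})

test_that("octave binning splits boundary abundances between octaves", {
    oct <- prestonOctaves(c(1, 2, 3, 4, 7, 8))
    # 1, 2, 4, 8 sit on boundaries and are split half-and-half
    expect_equal(sum(oct$freq), 6)
    expect_equal(oct$freq[oct$octave == 0], 0.5)             # half of "1"
    expect_equal(oct$freq[oct$octave == 1], 0.5 + 0.5)       # 1's + 2's halves
    expect_equal(oct$freq[oct$octave == 2], 0.5 + 1 + 0.5)   # 2,3,4
    expect_equal(oct$freq[oct$octave == 3], 0.5 + 1 + 0.5)   # 4,7,8
})

test_that("preston estimates a fully censused lognormal community", {
    set.seed(91)
    ab <- pmax(1, round(stats::rlnorm(300, meanlog = 4, sdlog = 1)))
    fit <- prestonRichness(ab)
    expect_s4_class(fit, "PrestonFit")
    expect_equal(fit@veiledRichness,
        fit@modeHeight * fit@width * sqrt(2 * pi))
    # no veil: the whole Gaussian is visible, so area ~ S_obs
    expect_lt(abs(richness(fit) - 300) / 300, 0.05)
    expect_gte(richness(fit), fit@sObs)
    expect_error(prestonRichness(c(5)), "at least 3 occupied octaves")
})

test_that("abundance estimators refuse incidence data explicitly", {
    inc <- IncidenceMatrix(rbind(T1 = c(a = 1, b = 0), T2 = c(a = 1, b = 1)))
    expect_error(chao1(inc), "abundance data")
    expect_error(ace(inc), "abundance data")
    expect_error(prestonRichness(inc), "abundance data")
})

test_that("estimateRichness routes estimators and degrades gracefully", {
    set.seed(13)
    x <- AbundanceMatrix(randomCountMatrix(5, 20))
    df <- estimateRichness(x, methods = c("chao1", "chao2", "jack1"))
    expect_equal(df$estimator, c("chao1", "chao2", "jack1"))
    expect_true(all(df$point >= df$sObs - 1e-9))
    expect_equal(df$pointRounded, floor(df$point + 0.5))
    # incidence input: abundance estimators become NA rows, not errors
    inc <- asIncidence(x)
    expect_message(df2 <- estimateRichness(inc,
        methods = c("chao1", "chao2")), "requires abundance")
    expect_true(is.na(df2$point[df2$estimator == "chao1"]))
    expect_false(is.na(df2$point[df2$estimator == "chao2"]))
    # plug-in hook for externally defined estimators
    df3 <- estimateRichness(x, methods = "chao1",
        extra = list(constant = function(z)
            faunest::chapmanMR(nSpecies(z), nSpecies(z), nSpecies(z))))
    expect_true("constant" %in% df3$estimator)
})
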