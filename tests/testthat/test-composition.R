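# Shared fixture: a small incidence matrix with a taxon trait table and an
# ordered site grouping, mimicking traps assigned to biogeographic zones.
makeCompositionFixture <- function(seed = 1, nSites = 12, nSpecies = 80,
                                   nGroups = 3) {
    set.seed(seed)
    p <- matrix(runif(nSites * nSpecies) < 0.4, nSites, nSpecies,
        dimnames = list(paste0("T", seq_len(nSites)),
            paste0("sp", seq_len(nSpecies))))
    p[1, ] <- p[1, ] | c(TRUE, rep(FALSE, nSpecies - 1))
    x <- IncidenceMatrix(p, dropEmpty = FALSE)
    traits <- data.frame(species = colnames(p),
        order = sample(c("Diptera", "Hymenoptera"), nSpecies, TRUE))
    groups <- stats::setNames(
        rep(paste0("zone", seq_len(nGroups)), length.out = nSites),
        rownames(p))
    list(x = x, traits = traits, groups = groups)
}

test_that("per-group proportions pool sites and count distinct species", {
    # one group, every species Diptera: proportion 1
    m <- IncidenceMatrix(rbind(T1 = c(a = 1, b = 1), T2 = c(a = 1, b = 0)))
    traits <- data.frame(species = c("a", "b"), order = "Diptera")
    expect_equal(unname(proportionByGroup(m, traits,
        c(T1 = "g1", T2 = "g1"), "order", "Diptera")), 1)
    # two disjoint groups, sets {D,D,H} and {D,H,H}
    m2 <- IncidenceMatrix(rbind(
        T1 = c(d1 = 1, d2 = 1, h1 = 1, d3 = 0, h2 = 0, h3 = 0),
        T2 = c(d1 = 0, d2 = 0, h1 = 0, d3 = 1, h2 = 1, h3 = 1)))
    traits2 <- data.frame(species = c("d1", "d2", "d3", "h1", "h2", "h3"),
        order = c("Diptera", "Diptera", "Diptera", "Hym", "Hym", "Hym"))
    pr <- proportionByGroup(m2, traits2, c(T1 = "g1", T2 = "g2"),
        "order", "Diptera")
    expect_equal(unname(pr), c(2 / 3, 1 / 3))
    # species missing the trait are excluded with a warning
    traits3 <- traits2[-1, ]
    expect_warning(pr3 <- proportionByGroup(m2, traits3,
        c(T1 = "g1", T2 = "g2"), "order", "Diptera"), "missing trait")
    expect_equal(unname(pr3), c(1 / 2, 1 / 3))
    # unassigned site is an error
    expect_error(proportionByGroup(m2, traits2, c(T1 = "g1"),
        "order", "Diptera"), "assigned")
})

test_that("permutation test handles degenerate and constant cases", {
    fx <- makeCompositionFixture()
    # one group only: validation error
    expect_error(permutationTest(fx$x, fx$traits,
        stats::setNames(rep("g", 12), paste0("T", 1:12)),
        "order", "Diptera", seed = 1), "at least 2")
    # statistic constant under permutations (all species share the trait):
    # p must be 1
    traits1 <- data.frame(species = fx$traits$species, order = "Diptera")
    pt <- permutationTest(fx$x, traits1, fx$groups, "order", "Diptera",
        nPermutations = 200, seed = 5)
    expect_equal(pt@pValue, 1)
    # p respects the Monte-Carlo lower bound 1/(n+1)
    expect_gte(pt@pValue, 1 / 201)
})

test_that("exhaustive mode matches brute-force enumeration on 4 traps", {
    m <- IncidenceMatrix(rbind(
        T1 = c(a = 1, b = 1, c = 0, d = 0),
        T2 = c(a = 1, b = 0, c = 1, d = 0),
        T3 = c(a = 0, b = 0, c = 1, d = 1),
        T4 = c(a = 0, b = 1, c = 0, d = 1)))
    traits <- data.frame(species = c("a", "b", "c", "d"),
        order = c("Diptera", "Diptera", "Hym", "Hym"))
    groups <- c(T1 = "g1", T2 = "g1", T3 = "g2", T4 = "g2")
    pt <- permutationTest(m, traits, groups, "order", "Diptera",
        exhaustive = TRUE)
    expect_equal(pt@nPermutations, 6)   # choose(4,2) distinct assignments
    # independent brute force over the 6 assignments
    prop <- function(sites) {
        pres <- colSums(presence(m)[sites, , drop = FALSE]) > 0
        mean(traits$order[pres] == "Diptera")
    }
    combos <- utils::combn(4, 2)
    stats <- apply(combos, 2, function(g1)
        prop(setdiff(1:4, g1)) - prop(g1))
    obs <- prop(3:4) - prop(1:2)
    dir <- if (obs >= 0) 1 else -1
    pExact <- mean(stats * dir >= obs * dir - 1e-12)
    expect_equal(pt@pValue, pExact)
    expect_equal(sort(pt@nullStats), sort(stats))
})

test_that("Monte-Carlo p-values approximate the exhaustive ones", {
    fx <- makeCompositionFixture(seed = 3, nSites = 6, nSpecies = 30,
        nGroups = 2)
    pe <- permutationTest(fx$x, fx$traits, fx$groups, "order", "Diptera",
        exhaustive = TRUE)
    pm <- permutationTest(fx$x, fx$traits, fx$groups, "order", "Diptera",
        nPermutations = 4000, seed = 9)
    expect_lt(abs(pe@pValue - pm@pValue), 0.05)
})

test_that("trend statistic is the least-squares slope over group ranks", {
    fx <- makeCompositionFixture(seed = 4)
    pt <- permutationTest(fx$x, fx$traits, fx$groups, "order", "Diptera",
        statistic = "trend", nPermutations = 100, seed = 2)
    props <- proportionByGroup(fx$x, fx$traits, fx$groups, "order",
        "Diptera")
    k <- seq_along(props)
    expect_equal(pt@observed, unname(stats::coef(stats::lm(props ~ k))[2]))
})

test_that("species-area exponent matches its closed form", {
    expect_equal(speciesAreaExponent(100, 10000), 0.5)
    expect_equal(speciesAreaExponent(450, 450), 1)
    expect_equal(speciesAreaExponent(1, 1000), 0)
    expect_error(speciesAreaExponent(0.5, 10), "richness")
    expect_error(speciesAreaExponent(10, 1), "area")
})

test_that("area-controlled regression recovers planted structure", {
    set.seed(17)
    n <- 12
    area <- exp(runif(n, 8, 13))
    lat <- seq(40, 68, length.out = n)
    # exact power law, latitude shuffled: residuals ~ 0, slope ~ 0
    tab <- data.frame(country = paste0("C", 1:n),
        richness = 3 * area^0.25, area = area, latitude = sample(lat))
    fit <- areaControlledRichness(tab)
    expect_lt(max(abs(fit$residuals)), 1e-10)
    expect_lt(abs(fit$latitudeSlope), 1e-10)
    # planted negative latitude effect: slope sign recovered
    tab2 <- tab
    tab2$latitude <- lat
    tab2$richness <- 3 * area^0.25 * exp(-0.04 * (lat - 54) +
        rnorm(n, 0, 0.05))
    fit2 <- areaControlledRichness(tab2)
    expect_lt(fit2$latitudeSlope, 0)
    expect_lt(fit2$latitudePValue, 0.05)
    # planted outliers (undersized faunas at the highest latitudes) create an
    # apparent gradient; excluding them removes it
    set.seed(18)
    tab3 <- tab
    tab3$latitude <- lat
    tab3$richness <- 3 * area^0.25 * exp(rnorm(n, 0, 0.03))
    tab3$richness[10:12] <- tab3$richness[10:12] * 0.4
    fit3 <- areaControlledRichness(tab3)
    fit3x <- areaControlledRichness(tab3,
        exclude = c("C10", "C11", "C12"))
    expect_lt(fit3$latitudePValue, 0.05)
    expect_lt(fit3$latitudeSlope, 0)
    expect_gt(fit3x$latitudePValue, 0.05)
    expect_equal(length(fit3x$residuals), n - 3)
    expect_error(areaControlledRichness(tab[1:2, ]), "at least 3")
})
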