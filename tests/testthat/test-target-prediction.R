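rcOf <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))

test_that("position classifier covers all 16 base oppositions", {
    for (m in c("A", "C", "G", "T")) for (t in c("A", "C", "G", "T")) {
        mir <- paste0(m, "GGGGGGGGGGGGGGGGGGGG")   # pos 1 = tested pair
        site <- paste0(rcOf(substr(mir, 2, 21)), t)
        ds <- scoreDuplex(mir, site)
        expect_equal(duplexStatus(ds)[1], oracleDuplex(mir, site)[1],
                     info = paste(m, t))
    }
})

test_that("duplex scoring arithmetic: perfect, wobble, oracle sample", {
    m <- "TGACAGAAGAGAGTGAGCAC"
    ds <- scoreDuplex(m, rcOf(m))
    expect_equal(duplexTotal(ds), 0)
    expect_true(all(duplexStatus(ds) == "match"))
    expect_equal(ds@duplexEnergy, ds@perfectEnergy)

    ## one G:U at position 3 (miRNA A->G against site T), rest perfect
    m2 <- "AAACCCCCCCCCCCCCCCCC"
    site <- rcOf(m2)
    m2w <- m2; substr(m2w, 3, 3) <- "G"  # G faces T -> wobble
    dsw <- scoreDuplex(m2w, site)
    expect_equal(duplexStatus(dsw)[3], "wobble")
    expect_equal(duplexTotal(dsw), 0.5)

    set.seed(121)
    for (i in 1:50) {
        mir <- randomDna(sample(20:22, 1))
        site <- mutatedSite(mir, sample(0:6, 1))
        ds <- scoreDuplex(mir, site)
        st <- oracleDuplex(mir, site)
        expect_equal(duplexStatus(ds), st)
        expect_equal(duplexTotal(ds),
                     sum(ifelse(st == "match", 0,
                                ifelse(st == "wobble", 0.5, 1))))
    }
})

test_that("1-nt bulges are gap-scored and larger indels refused", {
    m <- "AAACCCCCCCCCCCCCCCCC"
    site <- rcOf(m)
    ## target-side bulge: insert a base into the site
    siteB <- paste0(substr(site, 1, 10), "G", substr(site, 11, 20))
    dsb <- scoreDuplex(m, siteB)
    expect_equal(duplexTotal(dsb), 1)
    expect_true(all(duplexStatus(dsb) == "match"))
    ## the inserted base sits in a homopolymer run, so the chosen bulge
    ## placement is the 5'-most equivalent one; it must exist
    expect_gte(dsb@targetBulgeAfter, 0L)
    ## miRNA-side bulge: delete a site base
    siteD <- paste0(substr(site, 1, 9), substr(site, 11, 20))
    dsd <- scoreDuplex(m, siteD)
    expect_equal(sum(duplexStatus(dsd) == "gap"), 1)
    expect_equal(duplexTotal(dsd), 1)
    expect_error(scoreDuplex(m, substr(site, 1, 17)), "at most 1")
})

test_that("the six rules behave at their stated boundaries", {
    m <- "TGACAGAAGAGAGTGAGCAC"
    perfect <- applyRules(scoreDuplex(m, rcOf(m)))
    expect_true(perfect$accepted)
    expect_true(all(perfect$verdicts))
    expect_equal(length(perfect$verdicts), 6L)

    ## single mismatch at position 10: only the cleavage-site rule fails
    site10 <- rcOf(m)
    p <- nchar(m) - 10 + 1
    b <- strsplit(m, "")[[1]][10]
    wrong <- setdiff(c("A", "C", "G", "T"),
                     c(rcOf(b), if (b == "G") "T", if (b == "T") "G"))
    substr(site10, p, p) <- wrong[1]
    r10 <- applyRules(scoreDuplex(m, site10))
    expect_false(r10$accepted)
    expect_false(r10$verdicts[["clean_10_11"]])
    expect_true(all(r10$verdicts[names(r10$verdicts) != "clean_10_11"]))

    ## five wobbles at 2,4,6,8,12 -> window score exactly 2.5, rule 5
    ## rejects on the strict < boundary (10/11 kept clean)
    ## wobbles: miRNA A->G at those positions, each G facing a site T
    mir2 <- strsplit(strrep("A", 21), "")[[1]]
    for (p in c(2, 4, 6, 8, 12)) mir2[p] <- "G"
    mir2 <- paste(mir2, collapse = "")
    ds2 <- scoreDuplex(mir2, rcOf(strrep("A", 21)))
    expect_equal(sum(duplexStatus(ds2) == "wobble"), 5)
    expect_equal(ds2@window1to12, 2.5)
    r <- applyRules(ds2)
    expect_false(r$verdicts[["window_1_12_lt2.5"]])
    expect_false(r$accepted)

    ## wobble at position 10 violates rule 4 unless explicitly allowed
    mirW <- strsplit(strrep("A", 21), "")[[1]]; mirW[10] <- "G"
    dsW <- scoreDuplex(paste(mirW, collapse = ""), rcOf(strrep("A", 21)))
    expect_false(applyRules(dsW)$verdicts[["clean_10_11"]])
    expect_true(applyRules(dsW, rule4_allow_wobble = TRUE)$
                verdicts[["clean_10_11"]])
})

test_that("rule verdicts equal the brute-force re-implementation", {
    set.seed(131)
    n_checked <- 0
    for (i in 1:400) {
        mir <- randomDna(21)
        site <- mutatedSite(mir, sample(0:6, 1))
        ds <- scoreDuplex(mir, site)
        got <- applyRules(ds)
        st <- oracleDuplex(mir, site)
        ratio <- abs(ds@duplexEnergy) / abs(ds@perfectEnergy)
        exp <- oracleRules(st, ratio)
        expect_equal(unname(got$verdicts), exp, info = paste(mir, site))
        expect_equal(got$accepted, all(exp))
        n_checked <- n_checked + 1
    }
    expect_equal(n_checked, 400)
})

test_that("mutating a matched position never rescues a rejected duplex", {
    set.seed(141)
    for (i in 1:40) {
        mir <- randomDna(21)
        site <- mutatedSite(mir, sample(1:5, 1))
        before <- applyRules(scoreDuplex(mir, site))
        if (before$accepted) next
        matchPos <- which(oracleDuplex(mir, site) == "match")
        if (length(matchPos) == 0) next
        p <- sample(matchPos, 1)
        sp <- 22 - p
        cur <- substr(site, sp, sp)
        mb <- substr(mir, p, p)
        bad <- setdiff(c("A", "C", "G", "T"),
                       c(cur, if (mb == "G") "T", if (mb == "T") "G"))
        site2 <- site; substr(site2, sp, sp) <- bad[1]
        after <- applyRules(scoreDuplex(mir, site2))
        expect_false(after$accepted)
    }
})

test_that("transcript scanning finds exactly the planted sites", {
    m156 <- "TGACAGAAGAGAGTGAGCAC"
    tx <- paste0(randomDna(40), rcOf(m156), randomDna(40))
    hits <- scanTranscripts(m156, c(t1 = tx))
    expect_equal(nrow(hits), 1)
    expect_equal(hits$start, 41)
    expect_equal(hits$end, 60)
    expect_true(hits$accepted)

    ## all-A transcript vs a C/G-containing miRNA: nothing
    expect_equal(nrow(scanTranscripts(m156,
                                      c(t2 = strrep("A", 80)))), 0)

    ## exhaustive-scan oracle over transcripts with 0-3 mutations planted
    set.seed(151)
    for (i in 1:12) {
        mir <- randomDna(21)
        nmut <- sample(0:3, 1)
        site <- mutatedSite(mir, nmut)
        tx <- paste0(randomDna(30), site, randomDna(30))
        got <- scanTranscripts(mir, tx)
        ## oracle: test every window directly
        exp <- integer(0)
        for (st in 1:(nchar(tx) - 20)) {
            w <- substr(tx, st, st + 20)
            stt <- oracleDuplex(mir, w)
            e <- 0
            mb <- strsplit(mir, "")[[1]]
            tb <- rev(strsplit(w, "")[[1]])
            for (p in 1:21)
                e <- e + (function(a, b) {
                    v <- oraclePairEnergy(a, b); if (is.finite(v)) v else 0
                })(mb[p], tb[p])
            if (all(oracleRules(stt, abs(e) /
                                abs(sum(ifelse(mb %in% c("G", "C"),
                                               -3, -2))))))
                exp <- c(exp, st)
        }
        expect_equal(got$start, exp, info = mir)
    }

    expect_warning(scanTranscripts(m156, c(tiny = "ACGT")), "shorter")
})
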