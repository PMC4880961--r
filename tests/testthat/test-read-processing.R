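mkReads <- function(seqs) {
    data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs,
               qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}
A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("each constructed read lands in its category, in priority order", {
    ins21 <- "TTGACAGAAGATAGAGAGCAC"
    reads <- mkReads(c(
        paste0(ins21, A3),                        # clean
        strrep("CT", 25),                          # no adapter
        paste0(A3, "ACGTACGT"),                    # insert null
        paste0(substr(A5, 1, 8), "ACGTACGTACGT", A3),  # 5' contaminant
        paste0(strrep("A", 20), A3),               # polyA
        paste0("ACGTACGTACGTACGT", A3)))           # 16 nt -> short
    cl <- cleanReads(reads, A3, A5)
    expect_equal(cl$assignments$category,
                 c("clean", "adapter3_null", "insert_null",
                   "adapter5_contam", "polyA", "short_lt18"))
    expect_equal(as.character(cl$clean[[1]]), ins21)
    ## polyA precedes short: a 15-nt all-A insert is polyA, not short
    cl2 <- cleanReads(mkReads(paste0(strrep("A", 15), A3)), A3, A5)
    expect_equal(cl2$assignments$category, "polyA")
})

test_that("no read with the 3' adapter means everything is adapter3-null", {
    reads <- mkReads(c(strrep("CT", 25), strrep("GA", 25)))
    cl <- cleanReads(reads, A3, A5)
    cts <- cleaningCounts(cl$report)
    expect_equal(unname(cts[["adapter3_null"]]), 2)
    expect_equal(unname(cts[["clean"]]), 0)
})

test_that("low-quality and N-rich reads are dropped before categorisation", {
    reads <- data.frame(
        id = c("ok", "lowq", "nrich"),
        seq = c(paste0("TTGACAGAAGATAGAGAGCAC", A3),
                paste0("TTGACAGAAGATAGAGAGCAC", A3),
                paste0(strrep("N", 10), "AGATAGAGAGC", A3)),
        stringsAsFactors = FALSE)
    reads$qual <- strrep("I", nchar(reads$seq))
    reads$qual[2] <- strrep("#", nchar(reads$seq[2]))  # Q2
    cl <- cleanReads(reads, A3, A5)
    cts <- cleaningCounts(cl$report)
    expect_equal(unname(cts[["total_raw"]]), 3)
    expect_equal(unname(cts[["high_quality"]]), 1)
    expect_equal(cl$assignments$id, "ok")
})

test_that("synthetic categories agree with generator truth within 4 sigma", {
    cfg <- generatorConfig(n_reads = 20000, seed = 31)
    g <- generateReads(cfg)
    cl <- cleanReads(g$reads)
    cts <- cleaningCounts(cl$report)
    expect_equal(unname(cts[["high_quality"]]), 20000)
    for (k in names(cfg$category_fractions)) {
        expect_within_4sigma(unname(cts[[k]]), 20000,
                             cfg$category_fractions[[k]])
        ## and the per-read assignment matches the truth label exactly
    }
    m <- merge(g$truth, cl$assignments, by = "id")
    expect_gt(mean(m$category.x == m$category.y), 0.999)
})

test_that("category counts always sum to high_quality and cleaning is idempotent", {
    g <- generateReads(generatorConfig(n_reads = 3000, seed = 5))
    cl <- cleanReads(g$reads)
    cts <- cleaningCounts(cl$report)
    expect_equal(sum(cts[c("adapter3_null", "insert_null",
                           "adapter5_contam", "short_lt18", "polyA",
                           "clean")]),
                 unname(cts[["high_quality"]]))
    ## re-cleaning inserts with the adapter re-appended returns them all
    again <- mkReads(paste0(as.character(cl$clean), A3))
    cl2 <- cleanReads(again, A3, A5)
    expect_equal(unname(cleaningCounts(cl2$report)[["clean"]]),
                 length(cl$clean))
    expect_equal(sort(unname(as.character(cl2$clean))),
                 sort(unname(as.character(cl$clean))))
})

test_that("summarizeCleaning reproduces published-style accounting", {
    r <- summarizeCleaning(c(total_raw = 30000000,
                             high_quality = 29948480,
                             adapter3_null = 43776, insert_null = 5228,
                             adapter5_contam = 92262,
                             short_lt18 = 115751, polyA = 1429))
    cts <- cleaningCounts(r); pct <- cleaningPercentages(r)
    expect_equal(unname(cts[["clean"]]), 29690034)
    expect_equal(unname(pct[["clean"]]), 99.14)
    expect_equal(unname(pct[["adapter3_null"]]), 0.15)
    expect_equal(unname(pct[["insert_null"]]), 0.02)
    expect_equal(unname(pct[["adapter5_contam"]]), 0.31)
    expect_equal(unname(pct[["short_lt18"]]), 0.39)
    expect_equal(unname(pct[["polyA"]]), 0.00)
    expect_equal(unname(pct[["high_quality"]]), 100.00)
})

test_that("summarizeCleaning boundaries: zero removals and total removal", {
    r0 <- summarizeCleaning(c(high_quality = 1000, adapter3_null = 0,
                              insert_null = 0, adapter5_contam = 0,
                              short_lt18 = 0, polyA = 0))
    expect_equal(unname(cleaningCounts(r0)[["clean"]]), 1000)
    expect_equal(unname(cleaningPercentages(r0)[["clean"]]), 100.00)
    rAll <- summarizeCleaning(c(high_quality = 100, adapter3_null = 50,
                                insert_null = 0, adapter5_contam = 25,
                                short_lt18 = 25, polyA = 0))
    expect_equal(unname(cleaningCounts(rAll)[["clean"]]), 0)
    expect_equal(unname(cleaningPercentages(rAll)[["clean"]]), 0.00)
    expect_error(summarizeCleaning(c(high_quality = 10,
                                     adapter3_null = 20, insert_null = 0,
                                     adapter5_contam = 0, short_lt18 = 0,
                                     polyA = 0)), "exceed")
})

test_that("collapseUnique matches a brute-force counting oracle", {
    expect_equal(tagCounts(collapseUnique(rep("ACGTACGTACGTACGTAC", 5))),
                 5L)
    distinct <- vapply(1:20, function(i) randomDna(20), character(1))
    distinct <- unique(distinct)
    ts <- collapseUnique(distinct)
    expect_equal(length(ts), length(distinct))
    expect_true(all(tagCounts(ts) == 1L))

    set.seed(77)
    pool <- vapply(1:30, function(i) randomDna(sample(18:25, 1)),
                   character(1))
    reads <- sample(pool, 500, replace = TRUE)
    ts <- collapseUnique(reads)
    oracle <- sort(table(reads), decreasing = TRUE)
    expect_equal(sum(tagCounts(ts)), 500)
    for (s in names(oracle))
        expect_equal(tagCounts(ts)[as.character(tagSequences(ts)) == s],
                     as.integer(oracle[[s]]))
    ## ordering: count desc, then sequence asc
    o <- order(-tagCounts(ts), as.character(tagSequences(ts)))
    expect_equal(o, seq_along(o))
    ## round trip preserves the multiset
    expanded <- rep(as.character(tagSequences(ts)), tagCounts(ts))
    expect_equal(sort(expanded), sort(reads))
})

test_that("tag FASTA round-trips through the x-count header convention", {
    ts <- tagSet(c("ACGTACGTACGTACGTAC", "TTGACAGAAGATAGAGAGCAC"),
                 c(3L, 10L))
    f <- tempfile(fileext = ".fa")
    writeTagFasta(ts, f)
    back <- readTagFasta(f)
    expect_equal(as.character(tagSequences(back)),
                 as.character(tagSequences(ts)))
    expect_equal(tagCounts(back), tagCounts(ts))
    unlink(f)
})
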