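## Independent oracles, deliberately kept free of the package's own code
## paths: breadth-first search for connected components, a textbook two-pass
## Pearson correlation, and the closed-form adjusted Rand index.

bfsComponents <- function(pairs, allIds) {
    adj <- lapply(setNames(vector("list", length(allIds)), allIds), identity)
    if (!is.null(pairs) && nrow(pairs) > 0L) {
        for (i in seq_len(nrow(pairs))) {
            a <- pairs$idA[i]; b <- pairs$idB[i]
            adj[[a]] <- c(adj[[a]], b)
            adj[[b]] <- c(adj[[b]], a)
        }
    }
    comp <- setNames(rep(NA_integer_, length(allIds)), allIds)
    nextId <- 0L
    for (start in allIds) {
        if (!is.na(comp[[start]])) next
        nextId <- nextId + 1L
        queue <- start
        comp[[start]] <- nextId
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            for (w in adj[[v]]) {
                if (is.na(comp[[w]])) {
                    comp[[w]] <- nextId
                    queue <- c(queue, w)
                }
            }
        }
    }
    comp
}

pearsonTwoPass <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    num <- sum((x - mx) * (y - my))
    num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

ariClosedForm <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}

## random edge set over n nodes, for component-oracle comparisons
randomGraphCase <- function(n, pEdge = 0.08) {
    ids <- sprintf("V%02d", seq_len(n))
    all <- t(combn(ids, 2L))
    keep <- runif(nrow(all)) < pEdge
    list(ids = ids,
         pairs = data.frame(idA = all[keep, 1L], idB = all[keep, 2L],
                            stringsAsFactors = FALSE))
}
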