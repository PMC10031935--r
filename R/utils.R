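#' @importFrom stats median quantile rnorm runif rbinom rexp sd uniroot
#'   complete.cases model.matrix setNames
NULL

# canonical protein identifiers P001..Pnnn for simulated panels
proteinIdsFor <- function(n) sprintf("P%03d", seq_len(n))

# derive a stream-specific child seed from a base seed, kept below 2^31
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

# seeded fold assignment: a permutation of 1..nFolds recycled over n samples
foldAssignment <- function(n, nFolds, seed) {
  if (nFolds > n) stop("more folds than samples (", nFolds, " > ", n, ")")
  set.seed(seed)
  sample(rep(seq_len(nFolds), length.out = n))
}

# outcomes can be a Surv object or a data.frame(time, event); normalize to
# list(time=, event=)
asOutcome <- function(outcomes) {
  if (survival::is.Surv(outcomes)) {
    out <- list(time = as.numeric(outcomes[, "time"]),
                event = as.integer(outcomes[, "status"]))
  } else if (is.data.frame(outcomes) || is.list(outcomes)) {
    out <- list(time = as.numeric(outcomes$time),
                event = as.integer(outcomes$event))
  } else {
    stop("outcomes must be a Surv object or a data.frame(time, event)")
  }
  if (length(out$time) != length(out$event))
    stop("time and event lengths differ")
  if (any(!is.finite(out$time)) || any(out$time <= 0))
    stop("survival times must be finite and positive")
  if (!all(out$event %in% c(0L, 1L)))
    stop("event indicators must be 0/1")
  out
}

# matrix with samples in rows, checking protein availability
asSampleMatrix <- function(X, proteins = NULL) {
  X <- as.matrix(X)
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, colnames(X))
    if (length(missing))
      stop("proteins absent from X: ", paste(missing, collapse = ", "))
    X <- X[, proteins, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readTSV <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# full-precision number formatting so written cohorts round-trip exactly
fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
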