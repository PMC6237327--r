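# Shared fixtures built in code.

fig3_counts <- c(A = 58, B = 231, C = 37, D = 120, E = 71, F = 6,
                 G = 83, H = 40)

# one sample per timepoint, single animal
tiny_sheet <- function(times = c(0, 1, 2, 3, 6, 24)) {
  data.frame(sample_id = paste0("s", seq_along(times)),
             animal = 1L, time_h = times, batch = "b1",
             stringsAsFactors = FALSE)
}

# best-permutation agreement between a clustering and truth labels
# (exact assignment search; cluster and truth must have the same
# number of classes)
best_match_agreement <- function(cluster, truth) {
  ct <- table(cluster, truth)
  k <- nrow(ct)
  stopifnot(k == ncol(ct))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(k)))
    best <- max(best, sum(ct[cbind(seq_len(k), p)]))
  best / length(cluster)
}

extfile <- function(name) system.file("extdata", name,
                                      package = "strokeClock")
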