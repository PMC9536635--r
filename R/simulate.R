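#' Build a per-position sequence profile model from reads
#'
#' Records, per read length present in the input, the empirical
#' per-position nucleotide frequencies (read orientation) plus the
#' empirical length distribution. Reads containing N are excluded from the
#' profile and tallied.
#'
#' @param reads data.table with chrom, start, end, strand.
#' @param genome A `"genome"` object.
#' @param anchor Optional anchor constraint: a list
#'   `list(position = p, dinucleotides = c(...))` requiring one of the given
#'   2-mers at read-orientation positions p..p+1 of every simulated read
#'   (e.g. a dipyrimidine at the Damage-seq lesion position). A negative
#'   `position` counts from the 3' end: `-5` anchors positions
#'   (L-5, L-4) of a length-L read, the XR-seq lesion location.
#' @return A `"read_profile_model"`: `$lengths` (data.table length/prob),
#'   `$freq` (list, per length, of position x ACGT frequency matrices),
#'   `$anchor`, `$n_excluded`.
#' @export
build_profile <- function(reads, genome, anchor = NULL) {
  if (nrow(reads) == 0L) stop("cannot profile an empty read set")
  seqs <- read_sequences(genome, reads)
  hasN <- grepl("N", seqs, fixed = TRUE)
  n_excluded <- sum(hasN)
  seqs <- seqs[!hasN]
  if (length(seqs) == 0L) stop("all reads contain N")
  lens <- nchar(seqs)
  ltab <- table(lens)
  lengths <- data.table::data.table(length = as.integer(names(ltab)),
                                    prob = as.numeric(ltab) / length(lens))
  freq <- lapply(stats::setNames(lengths$length, lengths$length), function(L) {
    ss <- seqs[lens == L]
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(ss),
                                      baseOnly = TRUE)
    f <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])
    f / rowSums(f)
  })
  structure(list(lengths = lengths, freq = freq, anchor = anchor,
                 n_excluded = n_excluded),
            class = "read_profile_model")
}

#' @export
print.read_profile_model <- function(x, ...) {
  cat("read_profile_model:", nrow(x$lengths), "length(s)",
      paste0("[", min(x$lengths$length), "-", max(x$lengths$length), "]"),
      if (!is.null(x$anchor)) "with anchor constraint" else "", "\n")
  invisible(x)
}

#' Simulate sequence-context-matched random genomic reads
#'
#' Draws reads whose per-position nucleotide composition matches a profile
#' model, by rejection sampling: a candidate read of model-sampled length is
#' placed uniformly (over the genome, or inside a supplied background
#' fragment set) on a uniform strand, and accepted with probability
#' proportional to its composition-corrected likelihood ratio
#' `prod_p f_p(x_p) / bg(x_p)` divided by the maximum attainable value,
#' where `bg` is the genome's global base composition. The correction makes
#' the accepted per-position marginals match the profile rather than the
#' profile tilted by genomic composition. Candidates violating the model's
#' anchor constraint are rejected outright. Deterministic given `seed`.
#'
#' @param model A `"read_profile_model"`.
#' @param genome A `"genome"` object.
#' @param n Number of reads to simulate.
#' @param seed Integer seed (recorded in the result's attributes).
#' @param sampling_space `"genome"` or `"background_reads"`.
#' @param background data.table of background fragments (required when
#'   `sampling_space = "background_reads"`); each simulated read is a
#'   sub-interval of one background fragment, on the fragment's strand.
#' @param min_accept Error out if the running acceptance rate falls below
#'   this floor after a burn-in (default 1e-4).
#' @param calibrate Run a pilot round and correct the acceptance weights for
#'   residual per-position marginal mismatch caused by local composition
#'   heterogeneity of the sampling space (default TRUE).
#' @return data.table chrom, start, end, name, score, strand of `n` reads.
#' @export
simulate_reads <- function(model, genome, n, seed,
                           sampling_space = c("genome", "background_reads"),
                           background = NULL, min_accept = 1e-4,
                           calibrate = TRUE) {
  sampling_space <- match.arg(sampling_space)
  stopifnot(inherits(model, "read_profile_model"), n >= 1)
  if (sampling_space == "background_reads" && is.null(background))
    stop("background fragments required for sampling_space='background_reads'")

  # global genome base composition for the likelihood-ratio correction;
  # strand-symmetrized because candidates are drawn from both strands
  af <- Biostrings::alphabetFrequency(genome$seqs, baseOnly = TRUE, collapse = TRUE)
  bg <- (af[c("A", "C", "G", "T")] + af[c("T", "G", "C", "A")]) / 2
  names(bg) <- c("A", "C", "G", "T")
  bg <- bg / sum(bg)
  # per length: log-weight matrix and its max attainable sum
  logw <- lapply(model$freq, function(f) {
    w <- log(pmax(f, 1e-12)) - matrix(log(bg), nrow(f), 4L, byrow = TRUE)
    list(w = w, mx = sum(apply(w, 1L, max)))
  })

  chroms <- names(genome$lengths)
  clens <- as.numeric(genome$lengths)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  anchor <- model$anchor
  acc_rate <- NA_real_

  run_round <- function(n_target, logw) {
    out <- vector("list", 0L); got <- 0L
    proposed <- 0L; accepted <- 0L
    while (got < n_target) {
      batch <- max(2000L, as.integer((n_target - got) * 4L))
      L <- model$lengths$length[sample.int(nrow(model$lengths), batch,
                                           replace = TRUE,
                                           prob = model$lengths$prob)]
      if (sampling_space == "genome") {
        ci <- sample.int(length(chroms), batch, replace = TRUE,
                         prob = pmax(clens - max(model$lengths$length), 1))
        maxs <- clens[ci] - L
        keep <- maxs >= 0
        st <- floor(stats::runif(batch) * (maxs + 1))
        chrom <- chroms[ci]
        strand <- ifelse(stats::runif(batch) < 0.5, "+", "-")
      } else {
        bi <- sample.int(nrow(background), batch, replace = TRUE)
        blen <- background$end[bi] - background$start[bi]
        keep <- blen >= L
        st <- background$start[bi] +
          floor(stats::runif(batch) * pmax(blen - L + 1, 1))
        chrom <- background$chrom[bi]
        strand <- background$strand[bi]
      }
      cand <- data.table::data.table(chrom = chrom, start = as.integer(st),
                                     end = as.integer(st + L),
                                     strand = strand)[keep]
      if (nrow(cand) == 0L) { proposed <- proposed + batch; next }
      seqs <- read_sequences(genome, cand)
      u <- stats::runif(nrow(cand))
      accept <- logical(nrow(cand))
      for (Lv in unique(nchar(seqs))) {
        li <- which(nchar(seqs) == Lv)
        key <- as.character(Lv)
        if (!key %in% names(logw)) next
        chm <- matrix(base_idx[unlist(strsplit(seqs[li], ""), use.names = FALSE)],
                      nrow = length(li), byrow = TRUE)
        okN <- rowSums(chm == 0L) == 0L
        w <- logw[[key]]$w
        ll <- rep(-Inf, length(li))
        if (any(okN)) {
          pos <- matrix(rep(seq_len(Lv), each = sum(okN)), ncol = Lv)
          ll[okN] <- rowSums(matrix(w[cbind(as.vector(pos),
                                            as.vector(chm[okN, , drop = FALSE]))],
                                    ncol = Lv))
        }
        p_acc <- exp(ll - logw[[key]]$mx)
        p_acc[!is.finite(p_acc)] <- 0  # bases with zero background mass
        if (!is.null(anchor)) {
          apos <- if (anchor$position < 0L) Lv + anchor$position
                  else anchor$position
          di <- substr(seqs[li], apos, apos + 1L)
          p_acc[!di %in% anchor$dinucleotides] <- 0
        }
        accept[li] <- u[li] < p_acc
      }
      proposed <- proposed + batch
      accepted <- accepted + sum(accept)
      if (any(accept)) out[[length(out) + 1L]] <- cand[accept]
      got <- accepted
      if (proposed > max(5e4, 50 * n_target) && accepted / proposed < min_accept)
        stop("acceptance rate ", signif(accepted / proposed, 2),
             " below floor; the profile model is too constrained for this genome")
    }
    acc_rate <<- accepted / proposed
    data.table::rbindlist(out)[seq_len(n_target)]
  }

  if (calibrate) {
    # pilot round, then correct the proposal weights for residual marginal
    # mismatch (local composition heterogeneity tilts the raw acceptance)
    n_pilot <- max(5000L, as.integer(ceiling(n / 5)))
    pilot <- run_round(n_pilot, logw)
    pseqs <- read_sequences(genome, pilot)
    plens <- nchar(pseqs)
    for (key in names(logw)) {
      Lv <- as.integer(key)
      ss <- pseqs[plens == Lv]
      if (length(ss) < 200L) next
      cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(ss),
                                        baseOnly = TRUE)
      mhat <- t(cm[c("A", "C", "G", "T"), , drop = FALSE])
      mhat <- mhat / rowSums(mhat)
      adj <- log(pmax(model$freq[[key]], 1e-12)) - log(pmax(mhat, 1e-3))
      w <- logw[[key]]$w + adj
      logw[[key]] <- list(w = w, mx = sum(apply(w, 1L, max)))
    }
  }
  res <- run_round(n, logw)
  res[, `:=`(name = paste0("sim_", .I), score = 0)]
  data.table::setcolorder(res, c("chrom", "start", "end", "name", "score", "strand"))
  data.table::setattr(res, "seed", seed)
  data.table::setattr(res, "acceptance_rate", acc_rate)
  res[]
}
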