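# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles, sharing no code with the implementation.

# plain recursive edit distance (unit costs), memoized
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (substr(a, i, i) == substr(b, j, j)) 0L else 1L
    val <- min(rec(i - 1L, j) + 1L,
               rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + cost)
    memo[[key]] <- val
    val
  }
  rec(nchar(a), nchar(b))
}

# naive TF-IDF cosine over a small corpus: explicit loops, no linear algebra
oracle_cosine_matrix <- function(corpus, query) {
  docs <- strsplit(c(corpus, query), " ", fixed = TRUE)
  vocab <- unique(unlist(strsplit(corpus, " ", fixed = TRUE)))
  n <- length(corpus)
  idf <- sapply(vocab, function(t) {
    df <- sum(sapply(strsplit(corpus, " ", fixed = TRUE),
                     function(d) t %in% d))
    log((1 + n) / (1 + df)) + 1
  })
  weigh <- function(toks) {
    w <- sapply(vocab, function(t) sum(toks == t) * idf[[t]])
    nr <- sqrt(sum(w^2))
    if (nr > 0) w / nr else w
  }
  qv <- weigh(strsplit(query, " ", fixed = TRUE)[[1]])
  sapply(corpus, function(doc) {
    dv <- weigh(strsplit(doc, " ", fixed = TRUE)[[1]])
    if (all(qv == 0) || all(dv == 0)) 0 else
      sum(qv * dv) / (sqrt(sum(qv^2)) * sqrt(sum(dv^2)))
  })
}

# mid-P McNemar by exhaustive enumeration of all 2^n discordance outcomes
oracle_midp <- function(b, c) {
  n <- b + c
  if (n == 0L) return(1)
  m <- max(b, c)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  heads <- rowSums(grid)
  p_ge <- mean(heads >= m)
  p_eq <- mean(heads == m)
  min(1, 2 * p_ge - p_eq)
}

# max-then-floor formulation of the device-selection rule
oracle_best_device <- function(notice, candidates, floor = 60L,
                               start = 95L, step = 5L) {
  if (nrow(candidates) == 0L) return(NULL)
  scores <- vapply(seq_len(nrow(candidates)), function(i)
    score_pair(notice$device_norm, notice$commercial_norm,
               candidates$commercial_norm[i],
               candidates$catalogue_norm[i])$score, integer(1))
  if (max(scores) < floor) return(NULL)
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    num <- suppressWarnings(as.numeric(candidates$progressive_id[best]))
    best <- if (anyNA(num)) best[order(candidates$progressive_id[best])[1L]]
    else best[order(num)[1L]]
  }
  thresholds <- seq(start, floor, by = -step)
  list(device_id = candidates$progressive_id[best],
       score = scores[best],
       accepted_threshold = as.integer(
         thresholds[which(thresholds <= max(scores))[1L]]))
}

# small fixture: registry of three manufacturers / five devices
fixture_registry <- function() {
  reg <- data.frame(
    progressive_id  = c("1001", "1002", "1003", "2001", "3001"),
    manufacturer    = c("Acme Medical SpA", "Acme Medical SpA",
                        "Acme Medical SpA", "Beta Devices Srl",
                        "Gamma Imaging GmbH"),
    catalogue_code  = c("CT100", "CT200", "CT300", "BX55", "GI9"),
    commercial_name = c("Cardio Probe X1", "Cardio Pump Z9",
                        "Neuro Stim K3", "Beta Valve Q2",
                        "Gamma Scanner S7"),
    device_type     = "MD",
    emdn_code       = c("Z110401", "Z1104", "C0102", "P0908", "Z11"),
    stringsAsFactors = FALSE)
  class(reg) <- c("device_registry", "data.frame")
  reg
}

fixture_notices <- function() {
  nt <- data.frame(
    manufacturer     = c("Acme Medical SpA", "Beta Devices Srl",
                         "Gamma Imaging GmbH"),
    device           = c("Cardio Probe X1", "Beta Valve Q2",
                         "Gamma Scanner S7"),
    commercial_name  = c("Cardio Probe X1 CT100", "Beta Valve Q2 BX55",
                         "Gamma Scanner S7 GI9"),
    notice_type      = "MD",
    action           = "recall",
    reference_number = c("SN-1", "SN-2", "SN-3"),
    date             = as.Date(c("2015-03-01", "2016-07-15", "2015-11-30")),
    bdrmd            = c("1001", NA, NA),
    stringsAsFactors = FALSE)
  class(nt) <- c("notice_set", "data.frame")
  nt
}
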