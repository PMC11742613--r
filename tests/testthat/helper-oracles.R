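# Independently coded oracles, deliberately kept naive and separate from the
# package implementations they check.

# Plain-R mirror of the declared alignment scoring (match +1, mismatch -1,
# gap open -2, extend -1; diagonal-first tie rule).
r_align_global <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -2 - (i - 2)
    pX[i, 1] <- if (i == 2) 0L else 1L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -2 - (j - 2)
    pY[1, j] <- if (j == 2) 0L else 2L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) 1 else -1
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)          # first max: M, then X, then Y
      M[i, j] <- cand[k] + s
      pM[i, j] <- k - 1L
      xo <- M[i - 1, j] - 2
      xe <- X[i - 1, j] - 1
      if (xo >= xe) { X[i, j] <- xo; pX[i, j] <- 0L }
      else          { X[i, j] <- xe; pX[i, j] <- 1L }
      yo <- M[i, j - 1] - 2
      ye <- Y[i, j - 1] - 1
      if (yo >= ye) { Y[i, j] <- yo; pY[i, j] <- 0L }
      else          { Y[i, j] <- ye; pY[i, j] <- 2L }
    }
  }
  endv <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  st <- which.max(endv) - 1L
  score <- endv[st + 1L]
  i <- n; j <- m; matches <- 0L
  while (i > 0 || j > 0) {
    if (st == 0L) {
      prev <- pM[i + 1, j + 1]
      if (A[i] == B[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
      st <- prev
    } else if (st == 1L) {
      prev <- pX[i + 1, j + 1]
      i <- i - 1L
      st <- prev
    } else {
      prev <- pY[i + 1, j + 1]
      j <- j - 1L
      st <- prev
    }
  }
  list(score = score, matches = matches)
}

r_identity <- function(a, b) {
  # same canonical argument order as the package, so traceback tie
  # choices cannot differ between the two implementations
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  r_align_global(a, b)$matches / min(nchar(a), nchar(b))
}

# Brute-force greedy clustering using the R aligner.
oracle_cluster <- function(acc, seqs, c) {
  ord <- order(-nchar(seqs), acc)
  acc <- acc[ord]
  seqs <- seqs[ord]
  reps <- integer(0)
  members <- list()
  for (i in seq_along(acc)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (r_identity(seqs[i], seqs[reps[k]]) >= c) {
        members[[k]] <- c(members[[k]], acc[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- acc[i]
    }
  }
  stats::setNames(members, acc[reps])
}

# Naive letter counter for composition checks.
oracle_composition <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- vapply(trpcensus::AA_STANDARD,
                   function(a) sum(chars == a), numeric(1))
  list(percent = 100 * counts / sum(counts), counted_length = sum(counts))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# Minimal depth-profile wrapper for cohort-level tests on raw depth draws.
as_trp_profile <- function(z, accession = "SYN") {
  out <- data.frame(resno = seq_along(z), restype = "W", z = z,
                    region = trpcensus::classify_region(z),
                    included = TRUE, stringsAsFactors = FALSE)
  attr(out, "accession") <- accession
  class(out) <- c("depth_profile", class(out))
  out
}
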