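# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: the module-definition oracle works
# by character-level translation of the definition text into an R logical
# expression, and the dereplication oracle is a plain matrix-based greedy
# loop.

# ---- KEGG definition truth-table oracle ------------------------------------

# split a definition into top-level blocks (space at parenthesis depth 0)
oracle_top_blocks <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  blocks <- character()
  cur <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == " " && depth == 0L) {
      if (nzchar(cur)) blocks <- c(blocks, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (nzchar(cur)) blocks <- c(blocks, cur)
  blocks
}

# drop a "-"-prefixed factor (KO or balanced parenthesis group)
oracle_strip_optional <- function(s) {
  repeat {
    # -K##### not preceded by another '-' (keep '--' intact)
    s2 <- gsub("(?<!-)-K\\d{5}", "", s, perl = TRUE)
    # -( balanced group )
    m <- regexpr("(?<!-)-\\(", s2, perl = TRUE)
    if (m > 0) {
      start <- as.integer(m)
      chars <- strsplit(s2, "", fixed = TRUE)[[1]]
      depth <- 0L
      end <- NA_integer_
      for (i in (start + 1L):length(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") {
          depth <- depth - 1L
          if (depth == 0L) { end <- i; break }
        }
      }
      s2 <- paste0(substr(s2, 1L, start - 1L), substr(s2, end + 1L, nchar(s2)))
    }
    if (identical(s2, s)) return(s2)
    s <- s2
  }
}

# evaluate one block expression against a KO set
oracle_block_present <- function(block_text, kos) {
  s <- trimws(oracle_strip_optional(block_text))
  if (!nzchar(s)) return(TRUE) # block was entirely optional
  s <- gsub("--", "FALSE", s, fixed = TRUE)
  s <- gsub(",", "||", s, fixed = TRUE)
  s <- gsub("+", "&&", s, fixed = TRUE)
  s <- gsub(" +\\)", ")", s)
  s <- gsub("\\( +", "(", s)
  # remaining spaces are conjunctions within the block; && binds tighter
  # than || in R, matching comma-binds-looser-than-space in the grammar
  s <- gsub(" +", "&&", s)
  s <- gsub("(K\\d{5})", '("\\1" %in% kos)', s)
  eval(parse(text = s))
}

oracle_completeness <- function(text, kos) {
  blocks <- oracle_top_blocks(text)
  required <- blocks[!(startsWith(blocks, "-") & !startsWith(blocks, "--"))]
  mean(vapply(required, oracle_block_present, logical(1), kos = kos))
}

# all KOs mentioned in a definition
oracle_all_kos <- function(text) {
  unique(unlist(regmatches(text, gregexpr("K\\d{5}", text))))
}

# random definition strings over a small KO pool, for property tests
random_definition <- function(ko_pool = sprintf("K%05d", 1:9)) {
  ko <- function() sample(ko_pool, 1)
  block <- function() {
    switch(sample(5, 1),
      ko(),
      sprintf("(%s,%s)", ko(), ko()),
      sprintf("%s+%s", ko(), ko()),
      sprintf("%s+%s-%s", ko(), ko(), ko()),
      sprintf("(%s,%s %s)", ko(), ko(), ko())
    )
  }
  paste(replicate(sample(1:4, 1), block()), collapse = " ")
}

# ---- greedy dereplication oracle -------------------------------------------

# matrix-based re-implementation of score-ranked greedy clustering
oracle_greedy_derep <- function(mags, ani, ani_min, af_min) {
  ids <- mags$mag_id
  n <- length(ids)
  A <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  F_ <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(ani))) {
    a <- ani$mag_a[i]; b <- ani$mag_b[i]
    A[a, b] <- max(A[a, b], ani$ani[i]); A[b, a] <- A[a, b]
    F_[a, b] <- max(F_[a, b], ani$af[i]); F_[b, a] <- F_[a, b]
  }
  score <- mags$completeness - 5 * mags$contamination
  ord <- ids[order(-score, ids)]
  reps <- character()
  assignment <- character(n)
  names(assignment) <- ord
  for (id in ord) {
    hit <- NA_character_
    for (r in reps) {
      if (A[id, r] >= ani_min && F_[id, r] >= af_min) { hit <- r; break }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      assignment[id] <- id
    } else {
      assignment[id] <- hit
    }
  }
  assignment
}

# random quality + ANI tables for the dereplication property tests
random_derep_case <- function(n_mags) {
  ids <- sprintf("mag%02d", seq_len(n_mags))
  mags <- tibble::tibble(
    mag_id = ids,
    completeness = round(runif(n_mags, 50, 100), 1),
    contamination = round(runif(n_mags, 0, 8), 1)
  )
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < 0.6
  ani <- tibble::tibble(
    mag_a = pairs[keep, 1], mag_b = pairs[keep, 2],
    ani = round(runif(sum(keep), 85, 100), 2),
    af = round(runif(sum(keep), 0, 100), 2)
  )
  list(mags = mags, ani = ani)
}
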