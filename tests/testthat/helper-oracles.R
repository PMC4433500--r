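# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: ancestors by plain recursion, inbreeding by
# Wright's path-counting over common ancestors, chi-square via stats::.

# recursive DFS ancestor closure on a bare data frame
oracle_ancestors <- function(df, id) {
  rec <- function(x) {
    i <- match(x, df$id)
    out <- character(0)
    for (p in c(df$sire[i], df$dam[i])) {
      if (!is.na(p)) out <- union(out, c(p, rec(p)))
    }
    out
  }
  rec(id)
}

# all ancestor paths id -> ... -> stop_at (inclusive), as lists of ids
oracle_paths_up <- function(df, id, stop_at) {
  if (id == stop_at) return(list(id))
  i <- match(id, df$id)
  out <- list()
  for (p in c(df$sire[i], df$dam[i])) {
    if (is.na(p)) next
    for (tail in oracle_paths_up(df, p, stop_at))
      out[[length(out) + 1L]] <- c(id, tail)
  }
  out
}

# Wright's F by path counting: sum over common ancestors A and over pairs of
# parent-to-A paths that share only A of (1/2)^(n1+n2+1) * (1 + F_A)
oracle_inbreeding <- function(df, id) {
  i <- match(id, df$id)
  s <- df$sire[i]; d <- df$dam[i]
  if (is.na(s) || is.na(d)) return(0)
  common <- intersect(c(s, oracle_ancestors(df, s)),
                      c(d, oracle_ancestors(df, d)))
  total <- 0
  for (a in common) {
    fa <- oracle_inbreeding(df, a)
    for (p1 in oracle_paths_up(df, s, a)) {
      for (p2 in oracle_paths_up(df, d, a)) {
        if (length(intersect(p1, p2)) == 1L)  # share only A
          total <- total + 0.5^(length(p1) + length(p2) - 1) * (1 + fa)
      }
    }
  }
  total
}

# random valid pedigree data frame of n individuals (parents precede children)
random_pedigree_df <- function(n, p_has_parents = 0.7) {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  ids <- sprintf("I%02d", seq_len(n))
  for (i in seq_len(n)) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) && length(females) && stats::runif(1) < p_has_parents) {
      sire[i] <- ids[males[sample.int(length(males), 1)]]
      dam[i] <- ids[females[sample.int(length(females), 1)]]
    }
  }
  data.frame(id = ids, sire = sire, dam = dam, sex = sex,
             affection = "unknown", stringsAsFactors = FALSE)
}
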