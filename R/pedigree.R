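#' @keywords internal
"_PACKAGE"

SEX_LEVELS <- c("male", "female", "unknown")
AFFECTION_LEVELS <- c("affected", "unaffected", "unknown")
SEVERITY_LEVELS <- c("cat1", "cat2", "cat3", "unassessed")
MARKER_LEVELS <- c("HOM", "HET", "WT", "untyped")

#' Construct a pedigree object
#'
#' A pedigree is a validated collection of individuals (dogs) with parent
#' links, phenotype, and linked-marker genotype attributes. Most users will
#' build one with [read_pedigree()] or [simulate_pedigree()]; this constructor
#' accepts a data frame directly.
#'
#' @param individuals data frame with columns `id`, `sire`, `dam`, `sex`,
#'   `affection`, and optionally `onset_age`, `severity`, `strn`, `litter`,
#'   `import`, `group`. Missing parents are `NA` (or "0", which is converted).
#'   `sex` is one of `male`/`female`/`unknown`; `affection` one of
#'   `affected`/`unaffected`/`unknown`; `severity` `cat1`/`cat2`/`cat3`/
#'   `unassessed`; `strn` `HOM`/`HET`/`WT`/`untyped`.
#' @param validate stop on hard validation errors? When `FALSE` the object is
#'   returned unchecked (used internally by [validate_pedigree()]).
#' @return an object of class `pedigree`: a list with element `individuals`
#'   (the normalised data frame, one row per dog).
#' @export
pedigree <- function(individuals, validate = TRUE) {
  df <- as.data.frame(individuals, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  df$id <- as.character(df$id)
  norm_parent <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
    x
  }
  df$sire <- norm_parent(df$sire)
  df$dam <- norm_parent(df$dam)
  if (is.null(df$sex)) df$sex <- "unknown"
  if (is.null(df$affection)) df$affection <- "unknown"
  if (is.null(df$onset_age)) df$onset_age <- NA_real_
  if (is.null(df$severity)) df$severity <- "unassessed"
  if (is.null(df$strn)) df$strn <- "untyped"
  if (is.null(df$litter)) df$litter <- NA_character_
  if (is.null(df$import)) df$import <- FALSE
  if (is.null(df$group)) df$group <- NA_character_
  df$sex <- as.character(df$sex)
  df$affection <- as.character(df$affection)
  df$onset_age <- as.numeric(df$onset_age)
  df$severity <- as.character(df$severity)
  df$severity[is.na(df$severity)] <- "unassessed"
  df$strn <- as.character(df$strn)
  df$strn[is.na(df$strn)] <- "untyped"
  df$litter <- as.character(df$litter)
  df$import <- !is.na(df$import) & as.logical(df$import)
  df$group <- as.character(df$group)
  rownames(df) <- NULL
  obj <- structure(list(individuals = df), class = "pedigree")
  if (validate) {
    rep <- validate_pedigree(obj)
    if (length(rep$errors)) {
      msgs <- vapply(rep$errors, function(e)
        sprintf("[%s] %s: %s", e$code, e$id, e$message), character(1))
      stop("invalid pedigree:\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    }
  }
  obj
}

#' @export
print.pedigree <- function(x, ...) {
  df <- x$individuals
  cat(sprintf("<pedigree> %d individuals (%d founders, %d affected)\n",
              nrow(df), length(founders(x)),
              sum(df$affection == "affected")))
  invisible(x)
}

#' Number of individuals in a pedigree
#' @param ped a [pedigree()] object
#' @return integer count
#' @export
n_individuals <- function(ped) nrow(ped$individuals)

ped_df <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ped$individuals
}

ped_index <- function(ped) {
  df <- ped$individuals
  stats::setNames(seq_len(nrow(df)), df$id)
}

#' Validate a pedigree
#'
#' Checks the hard structural invariants (unique ids, resolvable or missing
#' parent references, acyclic child-to-parent graph, parent-sex consistency,
#' no self-parenting, known category codes) and the soft phenotype invariants
#' (onset age implies affected, severity category implies affected). Hard
#' violations are errors; soft ones and dangling phenotype rows are warnings.
#'
#' @param ped a `pedigree` (or a bare individuals data frame)
#' @return a `validation_report`: list with `errors` and `warnings`, each a
#'   list of `list(code, id, message)` records. Empty `errors` means every
#'   hard invariant holds.
#' @export
validate_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped, validate = FALSE)
  df <- ped$individuals
  errors <- list()
  warnings <- list()
  err <- function(code, id, msg)
    errors[[length(errors) + 1L]] <<- list(code = code, id = id, message = msg)
  wrn <- function(code, id, msg)
    warnings[[length(warnings) + 1L]] <<- list(code = code, id = id, message = msg)

  flag <- function(fun, sel, code, msg_fmt, msg_arg = NULL) {
    for (k in which(sel))
      fun(code, df$id[k],
          if (is.null(msg_arg)) msg_fmt else sprintf(msg_fmt, msg_arg[k]))
  }
  dup <- unique(df$id[duplicated(df$id)])
  for (d in dup) err("duplicate_id", d, "individual id occurs more than once")

  flag(err, !df$sex %in% SEX_LEVELS, "unknown_sex",
       "unknown sex code '%s'", df$sex)
  flag(err, !df$affection %in% AFFECTION_LEVELS, "unknown_affection",
       "unknown affection code '%s'", df$affection)
  flag(err, !df$severity %in% SEVERITY_LEVELS, "unknown_severity",
       "unknown severity code '%s'", df$severity)
  flag(err, !df$strn %in% MARKER_LEVELS, "unknown_genotype",
       "unknown marker genotype '%s'", df$strn)
  for (p in c("sire", "dam")) {
    pid <- df[[p]]
    flag(err, !is.na(pid) & pid == df$id, "self_parent",
         sprintf("individual is its own %s", p))
    flag(err, !is.na(pid) & pid != df$id & !pid %in% df$id,
         "unresolved_parent", paste0(p, " '%s' not present in pedigree"), pid)
  }
  flag(err, !is.na(df$onset_age) & df$onset_age < 0, "negative_onset",
       "onset age must be non-negative")
  flag(wrn, !is.na(df$onset_age) & df$affection != "affected",
       "onset_without_affection",
       "onset age recorded for a dog not marked affected")
  flag(wrn, df$severity != "unassessed" & df$affection != "affected",
       "severity_without_affection",
       "severity category recorded for a dog not marked affected")

  # sire/dam sex consistency
  sire_ids <- stats::na.omit(unique(df$sire))
  dam_ids <- stats::na.omit(unique(df$dam))
  for (s in intersect(sire_ids, df$id)) {
    sx <- df$sex[match(s, df$id)]
    if (!sx %in% c("male", "unknown"))
      err("sire_not_male", s, sprintf("referenced as sire but sex is '%s'", sx))
  }
  for (d in intersect(dam_ids, df$id)) {
    sx <- df$sex[match(d, df$id)]
    if (!sx %in% c("female", "unknown"))
      err("dam_not_female", d, sprintf("referenced as dam but sex is '%s'", sx))
  }

  cyc <- find_cycle(df)
  if (!is.null(cyc))
    err("cycle", cyc[1],
        sprintf("ancestry cycle detected: %s", paste(cyc, collapse = " -> ")))

  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat(sprintf("  ERROR [%s] %s: %s\n", e$code, e$id, e$message))
  for (w in x$warnings) cat(sprintf("  warn  [%s] %s: %s\n", w$code, w$id, w$message))
  invisible(x)
}

# Kahn-style elimination on child->parent edges; returns NULL or ids on a cycle
find_cycle <- function(df) {
  ids <- df$id
  n <- length(ids)
  sire_i <- match(df$sire, ids)
  dam_i <- match(df$dam, ids)
  # node removable when both parents already removed (or absent)
  removed <- logical(n)
  repeat {
    can <- !removed &
      (is.na(sire_i) | removed[ifelse(is.na(sire_i), 1L, sire_i)]) &
      (is.na(dam_i) | removed[ifelse(is.na(dam_i), 1L, dam_i)])
    if (!any(can)) break
    removed[can] <- TRUE
  }
  if (all(removed)) return(NULL)
  # walk parent edges from a surviving node to exhibit the cycle
  start <- which(!removed)[1]
  path <- integer(0)
  cur <- start
  seen <- integer(0)
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    path <- c(path, cur)
    nxt <- c(sire_i[cur], dam_i[cur])
    nxt <- nxt[!is.na(nxt) & !removed[nxt]]
    cur <- nxt[1]
  }
  ids[c(path[which(path == cur):length(path)], cur)]
}

#' Read a pedigree from PED + phenotype files
#'
#' The PED file follows PLINK text conventions: whitespace-delimited columns
#' `family id sire dam sex affection`, missing parent `0`, sex `1` = male /
#' `2` = female / `0` = unknown, affection `1` = unaffected / `2` = affected /
#' `0` or `-9` = unknown. The phenotype sidecar is a CSV keyed by `id` with
#' columns `affection, onset_age, severity, strn` and optional `litter`,
#' `import`, `group`; it carries what PED column 6 cannot (marker genotype,
#' severity category, onset age jointly). Sidecar values override PED
#' affection when both are given and non-missing.
#'
#' @param ped_path path to the PED file
#' @param pheno_path optional path to the phenotype/genotype CSV
#' @return a validated [pedigree()]; phenotype rows whose id is absent from
#'   the PED are reported as a warning.
#' @export
read_pedigree <- function(ped_path, pheno_path = NULL) {
  stopifnot(file.exists(ped_path))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 6)
    stop("PED file must have 6 columns: family id sire dam sex affection")
  names(ped)[1:6] <- c("family", "id", "sire", "dam", "sex_code", "aff_code")
  sex_map <- c(`1` = "male", `2` = "female", `0` = "unknown")
  if (any(!ped$sex_code %in% names(sex_map)))
    stop("unknown sex code(s) in PED: ",
         paste(unique(ped$sex_code[!ped$sex_code %in% names(sex_map)]),
               collapse = ", "))
  aff_map <- c(`1` = "unaffected", `2` = "affected", `0` = "unknown",
               `-9` = "unknown")
  if (any(!ped$aff_code %in% names(aff_map)))
    stop("unknown affection code(s) in PED")
  df <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                   sex = unname(sex_map[ped$sex_code]),
                   affection = unname(aff_map[ped$aff_code]),
                   stringsAsFactors = FALSE)
  extra_warn <- character(0)
  if (!is.null(pheno_path)) {
    stopifnot(file.exists(pheno_path))
    ph <- utils::read.csv(pheno_path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
    stopifnot("id" %in% names(ph))
    unref <- setdiff(ph$id, df$id)
    if (length(unref))
      extra_warn <- sprintf("phenotype rows for unknown id(s): %s",
                            paste(unref, collapse = ", "))
    ph <- ph[ph$id %in% df$id, , drop = FALSE]
    m <- match(df$id, ph$id)
    take <- function(col, default) {
      if (col %in% names(ph)) {
        v <- ph[[col]][m]
        v
      } else rep(default, nrow(df))
    }
    blank_na <- function(x) {
      x[!is.na(x) & x == ""] <- NA
      x
    }
    aff2 <- blank_na(take("affection", NA_character_))
    keep <- !is.na(aff2)
    df$affection[keep] <- aff2[keep]
    df$onset_age <- as.numeric(blank_na(take("onset_age", NA_real_)))
    df$severity <- blank_na(take("severity", NA_character_))
    df$strn <- blank_na(take("strn", NA_character_))
    df$litter <- blank_na(take("litter", NA_character_))
    imp <- take("import", NA)
    df$import <- !is.na(imp) & (imp == TRUE | imp == "TRUE" | imp == "1")
    df$group <- blank_na(take("group", NA_character_))
  }
  out <- pedigree(df)
  if (length(extra_warn)) warning(extra_warn, call. = FALSE)
  out
}

#' Write a pedigree to PED + phenotype files
#'
#' Inverse of [read_pedigree()]; `read_pedigree(write_pedigree(ped))`
#' round-trips all fields.
#'
#' @param ped a [pedigree()]
#' @param ped_path,pheno_path output paths
#' @return invisibly, the two paths
#' @export
write_pedigree <- function(ped, ped_path, pheno_path) {
  df <- ped_df(ped)
  sex_code <- c(male = "1", female = "2", unknown = "0")[df$sex]
  aff_code <- c(unaffected = "1", affected = "2", unknown = "0")[df$affection]
  pedtab <- data.frame(family = "FAM1", id = df$id,
                       sire = ifelse(is.na(df$sire), "0", df$sire),
                       dam = ifelse(is.na(df$dam), "0", df$dam),
                       sex = sex_code, affection = aff_code)
  utils::write.table(pedtab, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  ph <- data.frame(id = df$id, affection = df$affection,
                   onset_age = df$onset_age, severity = df$severity,
                   strn = df$strn, litter = df$litter,
                   import = df$import, group = df$group)
  utils::write.csv(ph, pheno_path, row.names = FALSE, na = "")
  invisible(c(ped_path, pheno_path))
}

#' Founders of a pedigree
#'
#' @param ped a [pedigree()]
#' @return character vector of ids with both parents missing
#' @export
founders <- function(ped) {
  df <- ped_df(ped)
  df$id[is.na(df$sire) & is.na(df$dam)]
}

#' Ancestors / descendants of an individual
#'
#' Transitive closure over parent (resp. child) edges, excluding the
#' individual itself. A missing parent side contributes nothing.
#'
#' @param ped a [pedigree()]
#' @param id individual id (must exist)
#' @return character vector of ids
#' @export
ancestors <- function(ped, id) {
  df <- ped_df(ped)
  if (!id %in% df$id) stop("unknown id: ", id)
  idx <- match(df$id, df$id)
  sire <- stats::setNames(df$sire, df$id)
  dam <- stats::setNames(df$dam, df$id)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    parents <- unique(stats::na.omit(c(sire[frontier], dam[frontier])))
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  setdiff(seen, id)
}

#' @rdname ancestors
#' @export
descendants <- function(ped, id) {
  df <- ped_df(ped)
  if (!id %in% df$id) stop("unknown id: ", id)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    kids <- df$id[(!is.na(df$sire) & df$sire %in% frontier) |
                    (!is.na(df$dam) & df$dam %in% frontier)]
    kids <- setdiff(unique(kids), seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  setdiff(seen, id)
}

# generation depth: founders 0, child = 1 + max(parent depths); vectorised
# wave relaxation, one pass per generation
ped_depth <- function(df) {
  n <- nrow(df)
  sire_i <- match(df$sire, df$id)
  dam_i <- match(df$dam, df$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(sire_i) & is.na(dam_i)] <- 0L
  side <- function(p_i) {
    v <- rep(-1L, n)
    k <- !is.na(p_i)
    v[k] <- depth[p_i[k]]
    v
  }
  while (anyNA(depth)) {
    ds <- side(sire_i)
    dd <- side(dam_i)
    can <- is.na(depth) & !is.na(ds) & !is.na(dd)
    if (!any(can)) stop("cycle detected while computing generation depth")
    depth[can] <- 1L + pmax(ds[can], dd[can])
  }
  depth
}

#' Kinship coefficient between two individuals
#'
#' Malecot kinship phi(a, b): probability that one allele sampled from each
#' is identical by descent, computed by the classical recursion over the
#' later-born individual's parents.
#'
#' @param ped a [pedigree()]
#' @param a,b individual ids
#' @return kinship coefficient in `[0, 1]`
#' @export
kinship_coefficient <- function(ped, a, b) {
  df <- ped_df(ped)
  stopifnot(a %in% df$id, b %in% df$id)
  depth <- ped_depth(df)
  sire <- stats::setNames(df$sire, df$id)
  dam <- stats::setNames(df$dam, df$id)
  dep <- stats::setNames(depth, df$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- if (x <= y) paste0(x, "\r", y) else paste0(y, "\r", x)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (x == y) {
      0.5 * (1 + phi(sire[[x]], dam[[x]]))
    } else {
      # recurse on the deeper (later) individual
      if (dep[[x]] < dep[[y]]) { tmp <- x; x <- y; y <- tmp }
      0.5 * (phi(sire[[x]], y) + phi(dam[[x]], y))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Wright's inbreeding coefficient
#'
#' F of an individual is the kinship coefficient of its parents; 0 when any
#' parent is missing (the missing side is an anonymous, unrelated founder).
#'
#' @param ped a [pedigree()]
#' @param id individual id
#' @return F in `[0, 1]`
#' @export
inbreeding_coefficient <- function(ped, id) {
  df <- ped_df(ped)
  stopifnot(id %in% df$id)
  i <- match(id, df$id)
  if (is.na(df$sire[i]) || is.na(df$dam[i])) return(0)
  kinship_coefficient(ped, df$sire[i], df$dam[i])
}

#' Litters of a pedigree
#'
#' Offspring sharing (sire, dam, litter key) form a litter; rows without a
#' recorded litter key fall back to one litter per (sire, dam) pair.
#'
#' @param ped a [pedigree()]
#' @return data frame with columns `sire`, `dam`, `litter`, `n`,
#'   `n_affected`, and a list-column `members`
#' @export
litters <- function(ped) {
  df <- ped_df(ped)
  off <- df[!is.na(df$sire) | !is.na(df$dam), , drop = FALSE]
  if (!nrow(off))
    return(data.frame(sire = character(0), dam = character(0),
                      litter = character(0), n = integer(0),
                      n_affected = integer(0)))
  key <- paste(ifelse(is.na(off$sire), "?", off$sire),
               ifelse(is.na(off$dam), "?", off$dam),
               ifelse(is.na(off$litter), "", off$litter), sep = "\r")
  sp <- split(seq_len(nrow(off)), key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(sire = off$sire[ix[1]], dam = off$dam[ix[1]],
               litter = off$litter[ix[1]], n = length(ix),
               n_affected = sum(off$affection[ix] == "affected"),
               stringsAsFactors = FALSE)
  }))
  out$members <- lapply(sp, function(ix) off$id[ix])
  rownames(out) <- NULL
  out
}
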