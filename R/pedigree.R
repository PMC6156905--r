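#' Construct and validate a pedigree
#'
#' A pedigree is a tibble with one row per individual and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id` (both `NA` for
#' founders) and `sex` (`"male"` or `"female"`). Validation enforces that
#' individual ids are unique, that each named parent exists in the same
#' family with the appropriate sex, that parents are either both present or
#' both missing, and that the parent relation is acyclic.
#'
#' @param data A data frame with the columns listed above (character ids).
#' @return A validated tibble of class `famgxm_pedigree`.
#' @examples
#' trio <- pedigree(data.frame(
#'   family_id = "F1", individual_id = c("A", "B", "C"),
#'   father_id = c(NA, NA, "A"), mother_id = c(NA, NA, "B"),
#'   sex = c("male", "female", "female")
#' ))
#' @export
pedigree <- function(data) {
  cols <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "famgxm_pedigree_error")
  }
  ped <- as_tibble(data)[cols]
  for (cc in cols) ped[[cc]] <- as.character(ped[[cc]])

  if (anyDuplicated(ped$individual_id)) {
    dup <- unique(ped$individual_id[duplicated(ped$individual_id)])
    abort(paste0("duplicate individual_id: ", paste(head(dup, 5), collapse = ", ")),
          class = "famgxm_pedigree_error")
  }
  if (!all(ped$sex %in% c("male", "female"))) {
    abort("sex must be \"male\" or \"female\"", class = "famgxm_pedigree_error")
  }
  half <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(half)) {
    abort(paste0("individuals with exactly one parent recorded: ",
                 paste(head(ped$individual_id[half], 5), collapse = ", ")),
          class = "famgxm_pedigree_error")
  }

  idx <- function(ids) match(ids, ped$individual_id)
  fa <- idx(ped$father_id)
  mo <- idx(ped$mother_id)
  bad_fa <- !is.na(ped$father_id) & is.na(fa)
  bad_mo <- !is.na(ped$mother_id) & is.na(mo)
  if (any(bad_fa | bad_mo)) {
    abort(paste0("parent referenced but absent from pedigree for: ",
                 paste(head(ped$individual_id[bad_fa | bad_mo], 5), collapse = ", ")),
          class = "famgxm_missing_member_error")
  }
  has_fa <- !is.na(fa)
  if (any(has_fa & ped$sex[fa] != "male") ||
      any(!is.na(mo) & ped$sex[mo] != "female")) {
    abort("father_id must name a male and mother_id a female",
          class = "famgxm_pedigree_error")
  }
  if (any(has_fa & ped$family_id[fa] != ped$family_id) ||
      any(!is.na(mo) & ped$family_id[mo] != ped$family_id)) {
    abort("parents must belong to the same family as their offspring",
          class = "famgxm_pedigree_error")
  }

  ped_topological_order(ped) # errors on cycles

  class(ped) <- c("famgxm_pedigree", class(ped))
  ped
}

#' @export
print.famgxm_pedigree <- function(x, ...) {
  cat(sprintf("<famgxm_pedigree: %d individuals in %d families>\n",
              nrow(x), length(unique(x$family_id))))
  NextMethod()
}

as_pedigree <- function(x) {
  if (inherits(x, "famgxm_pedigree")) x else pedigree(x)
}

# Kahn topological sort (parents before children), family-block contiguous.
# Returns row indices into `ped`; aborts on a cycle.
ped_topological_order <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    abort("cycle detected in pedigree parent relation",
          class = "famgxm_pedigree_cycle_error")
  }
  # stable sort by family keeps parents-before-children within each block
  ord[order(factor(ped$family_id[ord], levels = unique(ped$family_id)))]
}

#' Read / write pedigrees in PED format
#'
#' The PED dialect used is whitespace-delimited with five leading columns
#' `FID IID PAT MAT SEX`; a missing parent is coded `"0"`, sex is `1` (male)
#' or `2` (female). Columns beyond the fifth are ignored on read.
#' `write_ped()` followed by `read_ped()` is the identity up to whitespace.
#'
#' @param path Path to a PED file.
#' @return `read_ped()` returns a [pedigree()]; `write_ped()` returns `path`
#'   invisibly.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  fields <- lapply(keep, function(i) strsplit(trimws(lines[i]), "[ \t]+")[[1]])
  nf <- lengths(fields)
  if (any(nf < 5)) {
    abort(sprintf("malformed PED line %d: fewer than 5 fields", keep[which(nf < 5)[1]]),
          class = "famgxm_ped_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  sex_code <- m[, 5]
  bad_sex <- !sex_code %in% c("1", "2")
  if (any(bad_sex)) {
    abort(sprintf("unknown sex code '%s' on PED line %d",
                  sex_code[bad_sex][1], keep[which(bad_sex)[1]]),
          class = "famgxm_ped_parse_error")
  }
  if (anyDuplicated(m[, 2])) {
    i <- which(duplicated(m[, 2]))[1]
    abort(sprintf("duplicate IID '%s' on PED line %d", m[i, 2], keep[i]),
          class = "famgxm_ped_parse_error")
  }
  pedigree(tibble(
    family_id = m[, 1],
    individual_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = ifelse(sex_code == "1", "male", "female")
  ))
}

#' @param ped A [pedigree()].
#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  ped <- as_pedigree(ped)
  lines <- sprintf("%s %s %s %s %d",
                   ped$family_id, ped$individual_id,
                   ifelse(is.na(ped$father_id), "0", ped$father_id),
                   ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                   ifelse(ped$sex == "male", 1L, 2L))
  writeLines(lines, path)
  invisible(path)
}
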