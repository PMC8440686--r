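## 6-column PED dialect: FID IID PAT MAT SEX PHENO
## SEX: 1 = male, 2 = female, other -> warning + unknown.
## PHENO: 2 = affected, anything else unaffected.
## "0" in PAT/MAT means no parent recorded.

#' Read a pedigree file into a list of FamilyPedigree objects
#'
#' The index case of each family is the first affected member that is not a
#' parent of another member (falling back to the first affected member, with
#' a warning when the choice is ambiguous). Cyclic parentage is fatal.
#'
#' @param path 6-column whitespace-separated PED file
#' @return named list of [FamilyPedigree-class], keyed by family id
#' @export
readPed <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "character", "character"))
  out <- list()
  for (fid in unique(ped$fid)) {
    fam <- ped[ped$fid == fid, , drop = FALSE]
    sex <- c("1" = "male", "2" = "female")[fam$sex]
    if (any(is.na(sex))) {
      warning("unknown sex code in family ", fid, "; set to 'unknown'", call. = FALSE)
      sex[is.na(sex)] <- "unknown"
    }
    affected <- fam$pheno == "2"
    father <- ifelse(fam$pat == "0", NA_character_, fam$pat)
    mother <- ifelse(fam$mat == "0", NA_character_, fam$mat)
    checkAcyclicParentage(fam$iid, father, mother, fid)
    isParent <- fam$iid %in% c(father, mother)
    candidates <- which(affected & !isParent)
    if (!length(candidates)) candidates <- which(affected)
    if (!length(candidates)) {
      stop("family ", fid, " has no affected member to serve as index case",
           call. = FALSE)
    }
    if (length(candidates) > 1) {
      warning("family ", fid, ": multiple index candidates, taking first (",
              fam$iid[candidates[1]], ")", call. = FALSE)
    }
    members <- data.frame(
      experiment_id = fam$iid,
      sex = unname(sex),
      affected = affected,
      father_id = father,
      mother_id = mother,
      is_index = seq_len(nrow(fam)) == candidates[1],
      stringsAsFactors = FALSE
    )
    out[[fid]] <- FamilyPedigree(fid, members)
  }
  out
}

checkAcyclicParentage <- function(ids, father, mother, fid) {
  parentOf <- function(i) {
    p <- c(father[i], mother[i])
    match(p[!is.na(p)], ids)
  }
  for (start in seq_along(ids)) {
    seen <- integer()
    frontier <- start
    while (length(frontier)) {
      if (start %in% unlist(lapply(frontier, parentOf))) {
        stop("cyclic parentage in family ", fid, call. = FALSE)
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(lapply(frontier, parentOf)), seen)
    }
  }
  invisible(TRUE)
}

#' Write pedigrees back to a 6-column PED file
#' @param pedigrees list of [FamilyPedigree-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePed <- function(pedigrees, path) {
  lines <- character()
  for (p in pedigrees) {
    m <- pedMembers(p)
    sexCode <- c(male = "1", female = "2", unknown = "0")[m$sex]
    lines <- c(lines, paste(familyId(p), m$experiment_id,
                            ifelse(is.na(m$father_id), "0", m$father_id),
                            ifelse(is.na(m$mother_id), "0", m$mother_id),
                            sexCode, ifelse(m$affected, "2", "1"),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
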