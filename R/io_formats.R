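#' Read genotypes from PLINK PED/MAP text files
#'
#' Parses whitespace-delimited PED/MAP into a [geno_matrix()]. Dosages count
#' the coded allele of each SNP. The coded allele is taken from an allele
#' sidecar file (`<map_path>.alleles`, written by [write_ped_map()]) when
#' present; otherwise alleles are collected from the PED file and ordered
#' alphabetically with the later-sorting allele coded. The sidecar route is
#' preferred because a frequency-based convention would silently flip dosage
#' meaning between population subsets.
#'
#' `0 0` allele pairs are missing calls (PLINK convention); a half-missing
#' pair (`A 0`) is also treated as missing.
#'
#' @param ped_path path to the PED file (6 mandatory columns, then two
#'   allele columns per SNP).
#' @param map_path path to the MAP file (chromosome, snp id, genetic
#'   position, base-pair position).
#' @return A [geno_matrix()] with individuals in PED row order.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("chromosome", "snp_id", "cm", "position"))
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  widths <- lengths(fields)
  if (length(widths) && any(widths != expected)) {
    bad <- which(widths != expected)[1L]
    stop("PED parse error at line ", bad, ": expected ", expected,
         " fields, found ", widths[bad])
  }
  n <- length(fields)
  ids <- vapply(fields, function(f) f[2L], character(1))
  allele_chars <- c("A", "C", "G", "T", "0", "1", "2")

  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    al <- fields[[i]][-(1:6)]
    bad <- which(!al %in% allele_chars)
    if (length(bad)) {
      stop("PED parse error at line ", i, ": invalid allele character '",
           al[bad[1L]], "'")
    }
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }

  sidecar <- paste0(map_path, ".alleles")
  if (file.exists(sidecar)) {
    side <- read.table(sidecar, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("snp_id", "allele_a", "allele_b") %in% names(side))) {
      stop("allele sidecar must have columns snp_id, allele_a, allele_b")
    }
    if (!identical(as.character(side$snp_id), as.character(map_raw$snp_id))) {
      stop("allele sidecar snp ids do not match MAP")
    }
    allele_a <- side$allele_a
    allele_b <- side$allele_b
  } else {
    allele_a <- character(m)
    allele_b <- character(m)
    for (k in seq_len(m)) {
      obs <- sort(unique(c(a1[, k], a2[, k])))
      obs <- obs[obs != "0"]
      if (length(obs) == 0L) obs <- c("A", "N")
      if (length(obs) == 1L) obs <- c(obs, "N")
      if (length(obs) > 2L) {
        stop("SNP ", map_raw$snp_id[k], " has more than two alleles: ",
             paste(obs, collapse = "/"))
      }
      allele_a[k] <- obs[1L]
      allele_b[k] <- obs[2L]
    }
  }

  dos <- matrix(NA_real_, n, m)
  for (k in seq_len(m)) {
    miss <- a1[, k] == "0" | a2[, k] == "0"
    dk <- (a1[, k] == allele_b[k]) + (a2[, k] == allele_b[k])
    dk[miss] <- NA_real_
    valid <- !miss & (a1[, k] %in% c(allele_a[k], allele_b[k])) &
      (a2[, k] %in% c(allele_a[k], allele_b[k]))
    if (any(!miss & !valid)) {
      stop("SNP ", map_raw$snp_id[k],
           ": allele not matching sidecar/observed alleles")
    }
    dos[, k] <- dk
  }

  map <- data.frame(snp_id = as.character(map_raw$snp_id),
                    chromosome = as.character(map_raw$chromosome),
                    position = map_raw$position,
                    allele_a = allele_a, allele_b = allele_b,
                    coded_allele = allele_b,
                    stringsAsFactors = FALSE)
  geno_matrix(dos, ids, map)
}

#' Write genotypes as PLINK PED/MAP text files
#'
#' Writes the PED/MAP pair plus an allele sidecar (`<map_path>.alleles`)
#' that fixes the coded allele, so that [read_ped_map()] round-trips the
#' dosage table exactly. In the sidecar `allele_b` is always the coded
#' allele.
#'
#' @param g a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "geno_matrix"))
  map <- g$map
  # orient so the coded allele is written as allele_b
  other <- ifelse(map$coded_allele == map$allele_b, map$allele_a, map$allele_b)
  coded <- map$coded_allele

  map_out <- data.frame(map$chromosome, map$snp_id, 0, map$position)
  write.table(map_out, map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  side <- data.frame(snp_id = map$snp_id, allele_a = other, allele_b = coded,
                     stringsAsFactors = FALSE)
  write.table(side, paste0(map_path, ".alleles"), quote = FALSE, sep = "\t",
              row.names = FALSE)

  d <- g$dosages
  n <- nrow(d); m <- ncol(d)
  con <- file(ped_path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(n)) {
    al <- character(2L * m)
    di <- d[i, ]
    j1 <- seq(1L, 2L * m, by = 2L); j2 <- j1 + 1L
    al[j1] <- ifelse(is.na(di), "0", ifelse(di >= 1, coded, other))
    al[j2] <- ifelse(is.na(di), "0", ifelse(di == 2, coded, other))
    writeLines(paste(c(rownames(d)[i], rownames(d)[i], "0", "0", "0", "-9", al),
                     collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a phenotype table
#'
#' Expects a CSV with header columns `id`, `sex`, `line`, `measured_age`
#' (days), `measured_weight` (kg), `measured_backfat` (mm). Sex labels are
#' normalised to `male`/`female` (accepted: m/f, male/female, 1/2, any
#' case); line labels must be one of `small`, `medium`, `large` (the
#' Danish / Canadian / American line roles).
#'
#' @param csv_path path to the CSV file.
#' @return A data.frame of class `pheno_table`. Corrected traits (`age100`,
#'   `bf100`) are added later by [apply_corrections()].
#' @export
read_phenotypes <- function(csv_path) {
  if (!file.exists(csv_path)) stop("phenotype file not found: ", csv_path)
  ph <- read.csv(csv_path, stringsAsFactors = FALSE)
  required <- c("id", "sex", "line", "measured_age", "measured_weight",
                "measured_backfat")
  missing_cols <- setdiff(required, names(ph))
  if (length(missing_cols)) {
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  ph$id <- as.character(ph$id)
  if (anyDuplicated(ph$id)) {
    stop("duplicated phenotype ids: ",
         paste(unique(ph$id[duplicated(ph$id)]), collapse = ", "))
  }
  ph$sex <- normalize_sex(ph$sex, ph$id)
  bad_line <- !ph$line %in% c("small", "medium", "large")
  if (any(bad_line)) {
    stop("unknown line labels for ids: ",
         paste(ph$id[bad_line], collapse = ", "),
         " (expected small/medium/large)")
  }
  for (col in c("measured_age", "measured_weight", "measured_backfat")) {
    v <- suppressWarnings(as.numeric(ph[[col]]))
    bad <- is.na(v) | v <= 0
    if (any(bad)) {
      stop("non-positive or non-numeric ", col, " for ids: ",
           paste(ph$id[bad], collapse = ", "))
    }
    ph[[col]] <- v
  }
  class(ph) <- c("pheno_table", "data.frame")
  ph
}

normalize_sex <- function(sex, ids) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("m", "male", "1"), "male",
                ifelse(s %in% c("f", "female", "2"), "female", NA_character_))
  if (anyNA(out)) {
    stop("unknown sex labels for ids: ", paste(ids[is.na(out)], collapse = ", "))
  }
  out
}

#' Read a pedigree
#'
#' Expects a CSV with header columns `id`, `sire`, `dam`; `0`, empty string
#' or `NA` denote an unknown parent. Parents that are referenced but have no
#' row of their own are added as founder records. The result is
#' topologically sorted so every parent precedes its offspring; a parentage
#' cycle is an error naming one individual on the cycle.
#'
#' @param csv_path path to the CSV file.
#' @return A data.frame of class `pedigree_table` with columns `id`, `sire`,
#'   `dam` (`NA` = unknown), ancestors before descendants.
#' @export
read_pedigree <- function(csv_path) {
  if (!file.exists(csv_path)) stop("pedigree file not found: ", csv_path)
  pd <- read.csv(csv_path, stringsAsFactors = FALSE,
                 colClasses = "character")
  required <- c("id", "sire", "dam")
  missing_cols <- setdiff(required, names(pd))
  if (length(missing_cols)) {
    stop("pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  as_pedigree(pd)
}

#' Build a sorted pedigree from id/sire/dam records
#'
#' @param records data.frame with character columns `id`, `sire`, `dam`
#'   (`"0"`, `""` or `NA` = unknown parent).
#' @return A `pedigree_table` sorted ancestors-first.
#' @export
as_pedigree <- function(records) {
  pd <- data.frame(id = as.character(records$id),
                   sire = as.character(records$sire),
                   dam = as.character(records$dam),
                   stringsAsFactors = FALSE)
  pd$sire[pd$sire %in% c("0", "") | is.na(pd$sire)] <- NA_character_
  pd$dam[pd$dam %in% c("0", "") | is.na(pd$dam)] <- NA_character_
  if (anyDuplicated(pd$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(pd$id[duplicated(pd$id)]), collapse = ", "))
  }
  # implicit founders for parents without their own record
  parents <- setdiff(stats::na.omit(c(pd$sire, pd$dam)), pd$id)
  if (length(parents)) {
    pd <- rbind(data.frame(id = parents, sire = NA_character_,
                           dam = NA_character_, stringsAsFactors = FALSE), pd)
  }
  n <- nrow(pd)
  idx <- stats::setNames(seq_len(n), pd$id)
  si <- idx[pd$sire]; di <- idx[pd$dam]

  # Kahn topological sort, stable in input order
  n_pending <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order_out <- integer(0)
  ready <- which(n_pending == 0L)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      n_pending[ch] <- n_pending[ch] - 1L
      if (n_pending[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order_out) < n) {
    on_cycle <- pd$id[setdiff(seq_len(n), order_out)]
    stop("pedigree contains a parentage cycle involving: ", on_cycle[1L])
  }
  pd <- pd[order_out, , drop = FALSE]
  rownames(pd) <- NULL
  class(pd) <- c("pedigree_table", "data.frame")
  pd
}

#' Write cross-validation results as a tidy CSV
#'
#' @param results a `cv_result` data.frame from [run_repeated_cv()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cv_results <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
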