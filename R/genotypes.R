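#' Chromosome-to-region map of the genotyping design
#'
#' Pairs of chromosomes form the genotyped regions: chromosomes I and II are
#' region 1, III and IV region 2, V and X region 3.
#' @return named integer vector, chromosome label -> region.
#' @export
chromosomeRegionMap <- function() {
  c(I = 1L, II = 1L, III = 2L, IV = 2L, V = 3L, X = 3L)
}

.CALL_CODES <- c("REF", "ALT", "HET", "MISSING")

#' Read an individual-level genotype table
#'
#' Tab-separated with header; required columns `population`, `generation`,
#' `individual`, `region`, `chromosome`, `snp_id`, `position`, `call`
#' (one of REF/ALT/HET/MISSING). Positions are 1-based. Every row is either
#' parsed or reported as an error — malformed rows are never skipped
#' silently.
#'
#' @param path file path.
#' @param region_map chromosome -> region map; defaults to
#'   [chromosomeRegionMap()].
#' @return data.frame of SNP calls.
#' @export
readGenotypeTable <- function(path, region_map = chromosomeRegionMap()) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(population = "character",
                                     individual = "character",
                                     chromosome = "character",
                                     snp_id = "character",
                                     call = "character"))
  validateGenotypeTable(df, region_map)
}

#' Validate an in-memory genotype table
#'
#' Applies the same checks as [readGenotypeTable()]: required columns, valid
#' call codes, chromosome/region consistency, and that each individual is
#' genotyped in exactly one region.
#'
#' @param df data.frame of SNP calls.
#' @inheritParams readGenotypeTable
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateGenotypeTable <- function(df, region_map = chromosomeRegionMap()) {
  requireCols(df, c("population", "generation", "individual", "region",
                    "chromosome", "snp_id", "position", "call"),
              "genotype table")
  bad <- which(!df$call %in% .CALL_CODES)
  if (length(bad))
    stop("unknown call code '", df$call[bad[1]], "' in column 'call', row ",
         bad[1], call. = FALSE)
  unk <- which(!df$chromosome %in% names(region_map))
  if (length(unk))
    stop("unknown chromosome label '", df$chromosome[unk[1]], "', row ",
         unk[1], call. = FALSE)
  mism <- which(region_map[df$chromosome] != df$region)
  if (length(mism))
    stop("chromosome/region mismatch in row ", mism[1], ": chromosome ",
         df$chromosome[mism[1]], " is not in region ", df$region[mism[1]],
         call. = FALSE)
  ind <- paste(df$population, df$generation, df$individual, sep = "\r")
  nreg <- tapply(df$region, ind, function(r) length(unique(r)))
  if (any(nreg > 1L))
    stop("individual genotyped in more than one region: ",
         names(nreg)[which(nreg > 1L)[1]], call. = FALSE)
  df
}

#' Write a genotype table
#' @param df data.frame of SNP calls.
#' @param path output file path.
#' @export
writeGenotypeTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-control filtering of SNP calls
#'
#' Drops SNPs with a high fraction of genotyping failures (MISSING) or of
#' heterozygous calls, and individuals in which a high fraction of the
#' retained SNPs failed. Filtering alternates SNP-level and individual-level
#' passes until a fixpoint, so the result is idempotent: applying QC to its
#' own output changes nothing.
#'
#' @param calls genotype data.frame (see [readGenotypeTable()]).
#' @param snp_fail_threshold drop a SNP when its MISSING fraction exceeds
#'   this (default 0.30).
#' @param individual_fail_threshold drop an individual when the fraction of
#'   its retained SNPs that are MISSING exceeds this (default 0.25).
#' @param het_threshold drop a SNP when its HET fraction exceeds this
#'   (default 0.30).
#' @return list with `calls` (filtered data.frame) and `report` (dropped SNP
#'   ids, dropped individual ids, thresholds, rounds to convergence).
#' @export
applyQC <- function(calls, snp_fail_threshold = 0.30,
                    individual_fail_threshold = 0.25,
                    het_threshold = 0.30) {
  for (th in c(snp_fail_threshold, individual_fail_threshold, het_threshold))
    if (!is.numeric(th) || th <= 0 || th > 1)
      stop("thresholds must lie in (0, 1]")
  df <- calls
  dropped_snps <- character(0)
  dropped_inds <- character(0)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    changed <- FALSE
    miss_frac <- tapply(df$call == "MISSING", df$snp_id, mean)
    het_frac <- tapply(df$call == "HET", df$snp_id, mean)
    bad_snps <- names(miss_frac)[miss_frac > snp_fail_threshold |
                                 het_frac > het_threshold]
    if (length(bad_snps)) {
      dropped_snps <- union(dropped_snps, bad_snps)
      df <- df[!df$snp_id %in% bad_snps, , drop = FALSE]
      changed <- TRUE
    }
    if (!nrow(df)) stop("QC removed all SNPs")
    ind <- paste(df$population, df$generation, df$individual, sep = "\r")
    ind_fail <- tapply(df$call == "MISSING", ind, mean)
    bad_inds <- names(ind_fail)[ind_fail > individual_fail_threshold]
    if (length(bad_inds)) {
      dropped_inds <- union(dropped_inds, bad_inds)
      df <- df[!ind %in% bad_inds, , drop = FALSE]
      changed <- TRUE
    }
    if (!nrow(df)) stop("QC removed all individuals")
    if (!changed) break
  }
  list(calls = df,
       report = list(
         dropped_snps = sort(dropped_snps),
         dropped_individuals = sort(gsub("\r", "/", dropped_inds)),
         n_dropped_snps = length(dropped_snps),
         n_dropped_individuals = length(dropped_inds),
         thresholds = list(snp_fail = snp_fail_threshold,
                           individual_fail = individual_fail_threshold,
                           het = het_threshold),
         rounds = rounds))
}

#' Write a QC report as JSON
#' @param report the `report` element of [applyQC()]'s result.
#' @param path output file path.
#' @export
writeQcReport <- function(report, path) writeJson(report, path)

#' Chromosome-wide haplotypes from homozygous SNP calls
#'
#' For every individual and genotyped chromosome, builds the allele string
#' (0 = REF, 1 = ALT) over the retained SNPs ordered by position. Selfing
#' individuals are expected to be homozygous: any HET call at a retained SNP
#' excludes the individual (with a warning); up to `max_impute` MISSING calls
#' per chromosome are imputed to the major allele of the individual's
#' population sample at that SNP, more exclude the individual.
#'
#' @param calls QC-filtered genotype data.frame.
#' @param max_impute maximum MISSING calls imputed per chromosome
#'   (default 1).
#' @return data.frame with columns `population`, `generation`, `individual`,
#'   `region`, `chromosome`, `cwh` (allele string).
#' @export
callsToCwh <- function(calls, max_impute = 1L) {
  df <- calls
  ind <- paste(df$population, df$generation, df$individual, sep = "\r")
  ## exclude any individual with a residual HET call
  het_ind <- unique(ind[df$call == "HET"])
  if (length(het_ind)) {
    warning(length(het_ind),
            " individual(s) excluded: heterozygous call at a retained SNP")
    keep <- !ind %in% het_ind
    df <- df[keep, , drop = FALSE]
    ind <- ind[keep]
  }
  ## exclude individuals with > max_impute MISSING per chromosome
  indchr <- paste(ind, df$chromosome, sep = "\r")
  n_missing <- tapply(df$call == "MISSING", indchr, sum)
  bad_chr <- names(n_missing)[n_missing > max_impute]
  if (length(bad_chr)) {
    bad_ind <- unique(vapply(strsplit(bad_chr, "\r"), function(p)
      paste(p[1:3], collapse = "\r"), ""))
    warning(length(bad_ind),
            " individual(s) excluded: too many failed SNPs on a chromosome")
    keep <- !ind %in% bad_ind
    df <- df[keep, , drop = FALSE]
    ind <- ind[keep]
  }
  if (!nrow(df)) stop("no individuals left for haplotype construction")
  ## impute residual MISSING to the sample major allele at that SNP
  df$allele <- ifelse(df$call == "ALT", 1L, 0L)
  mi <- which(df$call == "MISSING")
  if (length(mi)) {
    sampsnp <- paste(df$population, df$generation, df$snp_id, sep = "\r")
    ok <- df$call %in% c("REF", "ALT")
    alt_frac <- tapply(df$allele[ok], sampsnp[ok], mean)
    major <- ifelse(is.na(alt_frac[sampsnp[mi]]), 0L,
                    as.integer(alt_frac[sampsnp[mi]] >= 0.5))
    df$allele[mi] <- major
  }
  df <- df[order(df$population, df$generation, df$individual,
                 df$chromosome, df$position), , drop = FALSE]
  key <- paste(df$population, df$generation, df$individual,
               df$chromosome, sep = "\r")
  first <- !duplicated(key)
  out <- df[first, c("population", "generation", "individual", "region",
                     "chromosome")]
  out$cwh <- vapply(split(df$allele, factor(key, levels = key[first])),
                    paste, "", collapse = "")
  rownames(out) <- NULL
  out
}

## FNV-1a 32-bit hash of a string, as 8 hex characters; exact mod-2^32
## arithmetic in doubles (split multiply keeps intermediates < 2^41)
.fnv1a <- function(s) {
  h <- 2166136261
  for (x in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, x)
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Content-derived region-wide haplotype identifier
#'
#' An RWH identifier is determined by its region and concatenated allele
#' string: `"R<region>:<8-hex hash>"`. Identical strings always map to the
#' same identifier; [cwhToRwh()] guards against hash collisions within a
#' dataset.
#'
#' @param region region number(s).
#' @param allele_string concatenated allele string(s) over the region's two
#'   chromosomes.
#' @return character vector of identifiers.
#' @export
rwhId <- function(region, allele_string) {
  u <- unique(allele_string)
  h <- vapply(u, .fnv1a, "")
  paste0("R", region, ":", h[match(allele_string, u)])
}

#' Region-wide haplotypes from chromosome-wide haplotype pairs
#'
#' Concatenates the two CWHs of an individual's genotyped region (chromosomes
#' ordered by label within the region) into the region-wide haplotype (RWH).
#' The RWH identifier is determined by the concatenated allele string.
#' Individuals with only one chromosome genotyped are excluded with a
#' warning.
#'
#' @param cwh data.frame from [callsToCwh()].
#' @return data.frame with columns `population`, `generation`, `individual`,
#'   `region`, `rwh_id`, `rwh` (the concatenated allele string).
#' @export
cwhToRwh <- function(cwh) {
  ind <- paste(cwh$population, cwh$generation, cwh$individual, sep = "\r")
  nchr <- tapply(cwh$chromosome, ind, function(x) length(unique(x)))
  bad <- names(nchr)[nchr != 2L]
  if (length(bad)) {
    warning(length(bad),
            " individual(s) excluded: region not fully genotyped",
            " (need both chromosomes)")
    keep <- !ind %in% bad
    cwh <- cwh[keep, , drop = FALSE]
    ind <- ind[keep]
  }
  if (!nrow(cwh)) stop("no fully genotyped individuals")
  cwh <- cwh[order(cwh$population, cwh$generation, cwh$individual,
                   cwh$chromosome), , drop = FALSE]
  key <- paste(cwh$population, cwh$generation, cwh$individual, sep = "\r")
  first <- !duplicated(key)
  out <- cwh[first, c("population", "generation", "individual", "region")]
  out$rwh <- vapply(split(cwh$cwh, factor(key, levels = key[first])),
                    paste, "", collapse = "")
  out$rwh_id <- rwhId(out$region, out$rwh)
  n_strings <- tapply(out$rwh, out$rwh_id,
                      function(x) length(unique(x)))
  if (any(n_strings > 1L))
    stop("RWH id hash collision between distinct allele strings; ",
         "affected id: ", names(n_strings)[which(n_strings > 1L)[1]])
  rownames(out) <- NULL
  out[, c("population", "generation", "individual", "region", "rwh_id",
          "rwh")]
}

## split "regime.replicate" population labels at the last dot
.splitPopulation <- function(population) {
  regime <- sub("\\.[^.]*$", "", population)
  replicate <- sub("^.*\\.", "", population)
  no_dot <- !grepl("\\.", population)
  replicate[no_dot] <- "1"
  regime[no_dot] <- population[no_dot]
  data.frame(regime = regime, replicate = replicate)
}

#' Tally region-wide haplotype counts
#'
#' Counts each RWH per (regime, replicate, generation, region). Replicate
#' structure is taken from an explicit `population_map`
#' (columns `population`, `regime`, `replicate`) or, failing that, parsed
#' from population labels of the form `"regime.replicate"`.
#'
#' @param rwh data.frame from [cwhToRwh()].
#' @param population_map optional data.frame mapping populations to regimes
#'   and replicates.
#' @return RWH count table: `regime`, `replicate`, `generation`, `region`,
#'   `rwh_id`, `count`. Counts per sample sum to the number of genotyped
#'   individuals for that region.
#' @export
tallyRwh <- function(rwh, population_map = NULL) {
  if (is.null(population_map)) {
    pr <- .splitPopulation(rwh$population)
  } else {
    requireCols(population_map, c("population", "regime", "replicate"),
                "population map")
    i <- match(rwh$population, population_map$population)
    if (anyNA(i)) stop("population map does not cover: ",
                       rwh$population[which(is.na(i))[1]])
    pr <- population_map[i, c("regime", "replicate")]
  }
  key <- paste(pr$regime, pr$replicate, rwh$generation, rwh$region,
               rwh$rwh_id, sep = "\r")
  agg <- table(key)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    regime = vapply(parts, `[`, "", 1),
    replicate = vapply(parts, `[`, "", 2),
    generation = as.integer(vapply(parts, `[`, "", 3)),
    region = as.integer(vapply(parts, `[`, "", 4)),
    rwh_id = vapply(parts, `[`, "", 5),
    count = as.integer(agg))
  rownames(out) <- NULL
  out[order(out$regime, out$replicate, out$generation, out$region,
            -out$count, out$rwh_id), ]
}

#' Distinct-haplotype summary per region
#'
#' Reports, per region, the number of distinct RWHs observed across the whole
#' table, and the product of those counts — a lower bound on the number of
#' lineages that segregated in the ancestral population, since a lineage is
#' one RWH per region.
#'
#' @param counts an RWH count table ([tallyRwh()]).
#' @return list with `distinct_per_region` (named integer vector) and
#'   `product` (their product).
#' @export
distinctRwhSummary <- function(counts) {
  per <- tapply(counts$rwh_id, counts$region,
                function(x) length(unique(x)))
  list(distinct_per_region = c(per), product = prod(per))
}

#' Group minor RWHs into per-region background classes
#'
#' Within each replicate population and region, RWHs are ranked by the
#' maximum frequency they reach across that replicate's genotyped
#' generations (ties broken by total count, then lexicographic id). The top
#' `top_k` are designated primary; all others are summed into a single
#' background pseudo-RWH per region (`H0R1`, `H0R2`, ...). Total counts are
#' conserved.
#'
#' @param counts RWH count table ([tallyRwh()]).
#' @param top_k number of primary RWHs per sample (default 3).
#' @return grouped table with the same columns plus `designation`
#'   ("primary"/"background"); background rows are aggregated.
#' @export
groupMinor <- function(counts, top_k = 3L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  pieces <- split(counts, paste(counts$regime, counts$replicate,
                                counts$region, sep = "\r"))
  out <- lapply(pieces, function(d) {
    size <- tapply(d$count, d$generation, sum)
    freq <- d$count / as.numeric(size[as.character(d$generation)])
    maxfreq <- tapply(freq, d$rwh_id, max)
    total <- tapply(d$count, d$rwh_id, sum)
    ids <- names(maxfreq)
    ord <- order(-maxfreq, -total[ids], ids)
    primary <- ids[ord][seq_len(min(top_k, length(ids)))]
    d$designation <- ifelse(d$rwh_id %in% primary, "primary", "background")
    bg <- d$designation == "background"
    if (any(bg)) {
      b <- d[bg, , drop = FALSE]
      bkey <- paste(b$regime, b$replicate, b$generation, b$region, sep = "\r")
      bsum <- tapply(b$count, bkey, sum)
      first <- !duplicated(bkey)
      brows <- b[first, , drop = FALSE]
      brows$count <- as.integer(bsum[bkey[first]])
      brows$rwh_id <- paste0("H0R", brows$region)
      if ("rwh" %in% names(brows)) brows$rwh <- NA_character_
      d <- rbind(d[!bg, , drop = FALSE], brows)
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$regime, out$replicate, out$generation, out$region,
            out$designation, -out$count, out$rwh_id), ]
}

#' Pool replicate-level counts to regime level
#'
#' Sums grouped RWH counts over the replicates of each regime (the model
#' assumes all replicates of a regime share the same deterministic
#' dynamics, so counts are exchangeable draws from the regime-level
#' frequencies). An RWH designated primary in any replicate stays primary
#' regime-wide. Epochs missing from some replicates are retained with the
#' replicates available.
#'
#' @param grouped grouped table from [groupMinor()].
#' @return regime-level table: `regime`, `generation`, `region`, `rwh_id`,
#'   `count`, `designation`.
#' @export
poolToRegime <- function(grouped) {
  key <- paste(grouped$regime, grouped$generation, grouped$region,
               grouped$rwh_id, sep = "\r")
  cnt <- tapply(grouped$count, key, sum)
  prim <- tapply(grouped$designation == "primary", key, any)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    regime = vapply(parts, `[`, "", 1),
    generation = as.integer(vapply(parts, `[`, "", 2)),
    region = as.integer(vapply(parts, `[`, "", 3)),
    rwh_id = vapply(parts, `[`, "", 4),
    count = as.integer(cnt),
    designation = ifelse(prim, "primary", "background"))
  rownames(out) <- NULL
  out[order(out$regime, out$generation, out$region, out$designation,
            -out$count, out$rwh_id), ]
}

#' Read / write RWH count tables
#'
#' Tab-separated, columns `regime`, `replicate`, `generation`, `region`,
#' `rwh_id`, `count` (plus any extra columns present).
#'
#' @param path file path.
#' @export
readRwhCounts <- function(path) {
  if (!file.exists(path)) stop("RWH count file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(regime = "character",
                                     rwh_id = "character"))
  requireCols(df, c("regime", "generation", "region", "rwh_id", "count"),
              "RWH count table")
  if (any(df$count < 0)) stop("negative count in RWH count table")
  df
}

#' @rdname readRwhCounts
#' @param counts an RWH count table.
#' @export
writeRwhCounts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
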