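# Genotype ingest and quality control: site/call filters (Phred quality,
# call missingness, read depth, allele balance) and the dual rarity filter
# requiring MAF < 0.1% in both the cohort and a reference panel.

#' QC thresholds
#'
#' Defaults follow exome-cohort practice: site Phred quality strictly above
#' 20, site call-missingness strictly below 10%, carrier read depth of at
#' least 7, and a heterozygous allele-balance threshold of 0.15 (discovery
#' profile) or 0.20 (validation profile). The rarity cutoff of 0.001 is
#' strict (a MAF of exactly 0.1% fails).
#'
#' @param profile `"discovery"` (allele balance 0.15) or `"validation"`
#'   (0.20); ignored when `min_allele_balance` is given explicitly.
#' @param min_quality exclusive Phred quality threshold.
#' @param max_missingness exclusive site call-missingness threshold.
#' @param min_depth inclusive carrier read-depth threshold.
#' @param min_allele_balance inclusive heterozygous allele-balance threshold.
#' @param maf_cutoff exclusive minor allele frequency cutoff.
#' @param ab_rule `"site"` keeps a site when at least one depth-passing
#'   carrier meets the allele-balance threshold (sub-threshold carriers are
#'   retained); `"call"` additionally drops sub-threshold heterozygous
#'   carrier calls.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(profile = c("discovery", "validation"),
                          min_quality = 20, max_missingness = 0.10,
                          min_depth = 7, min_allele_balance = NULL,
                          maf_cutoff = 0.001,
                          ab_rule = c("site", "call")) {
  profile <- match.arg(profile)
  ab_rule <- match.arg(ab_rule)
  if (is.null(min_allele_balance)) {
    min_allele_balance <- if (profile == "validation") 0.20 else 0.15
  }
  vb_check(min_quality >= 0 && max_missingness >= 0 && max_missingness <= 1 &&
             min_depth >= 0 && min_allele_balance >= 0 &&
             min_allele_balance <= 1 && maf_cutoff > 0 && maf_cutoff <= 0.5,
           "QC thresholds out of range", "vepbench_config_error")
  structure(list(profile = profile, min_quality = min_quality,
                 max_missingness = max_missingness, min_depth = min_depth,
                 min_allele_balance = min_allele_balance,
                 maf_cutoff = maf_cutoff, ab_rule = ab_rule),
            class = "qc_thresholds")
}

parse_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  vb_check(nrow(fix) > 0, "VCF contains no records", "vepbench_parse_error")
  samples <- colnames(gt)[-1]
  n_samp <- length(samples)
  vb_check(n_samp > 0, "VCF contains no sample columns",
           "vepbench_parse_error")

  sites <- list(); calls <- list()
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt); di <- match("DP", fmt); ai <- match("AD", fmt)
    if (is.na(gi)) {
      vb_error(sprintf("record %d (%s:%s): FORMAT lacks GT", i,
                       fix[i, "CHROM"], fix[i, "POS"]),
               "vepbench_parse_error")
    }
    parts <- strsplit(gt[i, -1], ":", fixed = TRUE)
    gts <- vapply(parts, `[`, character(1), gi)
    gts <- gsub("|", "/", gts, fixed = TRUE)
    missing <- is.na(gts) | substr(gts, 1, 1) == "."
    alleles <- strsplit(gts[!missing], "/", fixed = TRUE)
    dp <- if (!is.na(di)) {
      suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= di) p[di] else NA_character_, character(1))))
    } else rep(NA_integer_, n_samp)
    ad <- if (!is.na(ai)) {
      lapply(parts, function(p) {
        if (length(p) < ai || p[ai] %in% c(".", "")) return(NULL)
        suppressWarnings(as.numeric(strsplit(p[ai], ",", fixed = TRUE)[[1]]))
      })
    } else vector("list", n_samp)

    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    info <- fix[i, "INFO"]
    gene <- parse_info_field(info, "GENE")
    ref_af <- suppressWarnings(as.numeric(parse_info_field(info,
                                                           "GNOMAD_AF")))
    base_id <- unname(fix[i, "ID"])
    for (k in seq_along(alts)) {
      vid <- if (!is.na(base_id) && base_id != "." && length(alts) == 1) {
        base_id
      } else if (!is.na(base_id) && base_id != ".") {
        sprintf("%s_alt%d", base_id, k)
      } else {
        paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k],
              sep = ":")
      }
      dos <- integer(n_samp)
      dos[!missing] <- vapply(alleles, function(a)
        sum(a == as.character(k)), integer(1))
      carrier <- which(dos > 0L)
      if (length(carrier)) {
        ab <- vapply(carrier, function(j) {
          adj <- ad[[j]]
          if (is.null(adj) || length(adj) < k + 1) return(NA_real_)
          tot <- if (!is.na(dp[j]) && dp[j] > 0) dp[j] else sum(adj)
          if (is.na(tot) || tot <= 0) return(NA_real_)
          adj[k + 1] / tot
        }, numeric(1))
        calls[[length(calls) + 1L]] <- data.frame(
          participant_id = samples[carrier], variant_id = vid,
          dosage = dos[carrier], depth = unname(dp[carrier]),
          allele_balance = unname(ab), stringsAsFactors = FALSE)
      }
      sites[[length(sites) + 1L]] <- data.frame(
        variant_id = vid, gene_id = gene,
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], site_quality = qual,
        call_missingness = sum(missing) / n_samp,
        reference_maf = ref_af, stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, c(sites, list(make.row.names = FALSE)))
  calls <- if (length(calls)) {
    do.call(rbind, c(calls, list(make.row.names = FALSE)))
  } else {
    data.frame(participant_id = character(0), variant_id = character(0),
               dosage = integer(0), depth = integer(0),
               allele_balance = numeric(0), stringsAsFactors = FALSE)
  }
  if (all(is.na(calls$depth)) && nrow(calls)) {
    vb_log("DP absent from VCF: depth filter will auto-pass")
  }
  list(sites = sites, calls = calls, n_participants = n_samp,
       participant_ids = samples)
}

#' Read genotype calls and variant sites
#'
#' VCF input yields one site per alternate allele (multi-allelic records are
#' decomposed) with site quality taken from QUAL, call missingness computed
#' as the fraction of samples with missing genotype, gene label and
#' reference allele frequency from the INFO keys `GENE` / `GNOMAD_AF`, and
#' one carrier call per sample with nonzero dosage (allele balance from AD
#' over DP when present; absent DP/AD leave the corresponding fields NA,
#' which auto-pass their filters). Tabular input takes a long call table
#' (participant_id, variant_id, dosage, depth, allele_balance) plus a site
#' table.
#'
#' @param path VCF file, or call TSV when `format = "tsv"`.
#' @param format `"vcf"` or `"tsv"`.
#' @param sites_path site TSV (required for `format = "tsv"`).
#' @return `list(sites, calls, n_participants, participant_ids)`.
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"),
                           sites_path = NULL) {
  format <- match.arg(format)
  vb_check(file.exists(path), sprintf("file '%s' does not exist", path),
           "vepbench_io_error")
  if (format == "vcf") return(read_genotypes_vcf(path))
  vb_check(!is.null(sites_path) && file.exists(sites_path),
           "tsv format requires an existing sites_path",
           "vepbench_io_error")
  calls <- vb_read_tsv(path)
  sites <- vb_read_tsv(sites_path)
  need <- c("participant_id", "variant_id", "dosage")
  vb_check(all(need %in% names(calls)),
           "call TSV must have participant_id, variant_id, dosage",
           "vepbench_parse_error")
  if (!"depth" %in% names(calls)) calls$depth <- NA_integer_
  if (!"allele_balance" %in% names(calls)) calls$allele_balance <- NA_real_
  list(sites = sites, calls = calls,
       n_participants = length(unique(calls$participant_id)),
       participant_ids = sort(unique(calls$participant_id)))
}

#' Apply site and call quality filters
#'
#' A site passes when its Phred quality strictly exceeds `min_quality`, its
#' call missingness is strictly below `max_missingness`, and at least one
#' carrier call surviving the depth filter meets the allele-balance
#' threshold (homozygous-alt calls auto-pass allele balance; NA depth or
#' allele balance auto-pass their rule). Carrier calls with depth below
#' `min_depth` are dropped; sites left with no surviving carrier are
#' dropped. Per-filter drop counts are logged and returned.
#'
#' @param sites site data.frame (variant_id, site_quality,
#'   call_missingness, ...).
#' @param calls long carrier-call data.frame.
#' @param thresholds a [qc_thresholds()].
#' @return `list(sites, calls, drops)` restricted to passing records.
#' @export
apply_qc <- function(sites, calls, thresholds = qc_thresholds()) {
  vb_check(inherits(thresholds, "qc_thresholds"),
           "thresholds must come from qc_thresholds()",
           "vepbench_config_error")
  th <- thresholds
  carrier <- calls[calls$dosage >= 1L, , drop = FALSE]

  depth_ok <- is.na(carrier$depth) | carrier$depth >= th$min_depth
  n_depth_drop <- sum(!depth_ok)
  carrier <- carrier[depth_ok, , drop = FALSE]

  ab_ok <- carrier$dosage == 2L | is.na(carrier$allele_balance) |
    carrier$allele_balance >= th$min_allele_balance

  qual_pass <- !is.na(sites$site_quality) &
    sites$site_quality > th$min_quality
  miss_pass <- !is.na(sites$call_missingness) &
    sites$call_missingness < th$max_missingness
  has_ab_carrier <- sites$variant_id %in%
    unique(carrier$variant_id[ab_ok])

  pass <- qual_pass & miss_pass & has_ab_carrier
  drops <- c(site_quality = sum(!qual_pass),
             call_missingness = sum(qual_pass & !miss_pass),
             allele_balance_or_no_carrier =
               sum(qual_pass & miss_pass & !has_ab_carrier),
             low_depth_calls = n_depth_drop)

  out_sites <- sites[pass, , drop = FALSE]
  if (th$ab_rule == "call") {
    carrier <- carrier[ab_ok, , drop = FALSE]
  }
  out_calls <- carrier[carrier$variant_id %in% out_sites$variant_id, ,
                       drop = FALSE]
  rownames(out_sites) <- NULL
  rownames(out_calls) <- NULL
  vb_log(sprintf(
    "QC: %d/%d sites pass (quality drops %d, missingness %d, AB/no-carrier %d); %d low-depth calls dropped",
    nrow(out_sites), nrow(sites), drops[1], drops[2], drops[3], drops[4]))
  list(sites = out_sites, calls = out_calls, drops = drops)
}

#' Compute folded cohort minor allele frequency
#'
#' `cohort_maf = sum(dosage) / (2 * n_participants)`, folded to the minor
#' allele (frequencies above 0.5 map to their complement; a fixed site folds
#' to 0).
#'
#' @param calls long carrier-call data.frame with dosage.
#' @param n_participants cohort size.
#' @return data.frame (variant_id, cohort_maf), one row per variant present
#'   in `calls`.
#' @export
compute_cohort_maf <- function(calls, n_participants) {
  vb_check(is.numeric(n_participants) && n_participants >= 1,
           "n_participants must be >= 1", "vepbench_config_error")
  if (!nrow(calls)) {
    return(data.frame(variant_id = character(0), cohort_maf = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ac <- tapply(calls$dosage, calls$variant_id, sum)
  if (any(ac > 2 * n_participants)) {
    vb_error("allele count exceeds 2 * n_participants",
             "vepbench_data_error")
  }
  af <- as.numeric(ac) / (2 * n_participants)
  data.frame(variant_id = names(ac), cohort_maf = pmin(af, 1 - af),
             stringsAsFactors = FALSE)
}

#' Restrict to variants rare in both cohort and reference
#'
#' A site is retained only when its cohort MAF and its reference-panel MAF
#' are both strictly below `maf_cutoff`. A missing (NA) reference frequency
#' is treated as 0: absence from the reference panel implies the variant is
#' at most extremely rare there.
#'
#' @param sites site data.frame carrying `cohort_maf` and `reference_maf`.
#' @param thresholds a [qc_thresholds()].
#' @return The rare subset of `sites`.
#' @export
filter_rare <- function(sites, thresholds = qc_thresholds()) {
  vb_check("cohort_maf" %in% names(sites),
           "sites must carry a cohort_maf column (see compute_cohort_maf)",
           "vepbench_data_error")
  ref <- sites$reference_maf
  if (is.null(ref)) ref <- rep(0, nrow(sites))
  ref[is.na(ref)] <- 0
  keep <- sites$cohort_maf < thresholds$maf_cutoff &
    ref < thresholds$maf_cutoff
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  vb_log(sprintf("rarity filter: %d/%d sites rare in cohort and reference",
                 nrow(out), nrow(sites)))
  out
}
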