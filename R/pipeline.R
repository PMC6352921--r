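#' Default pipeline configuration
#'
#' Returns the configuration list for [runPipeline()], optionally
#' overridden by a YAML file and/or a named list.  All randomness in
#' the pipeline flows from the single \code{seed} via fixed offsets, so
#' re-running with the same configuration is bit-identical.
#'
#' @param path optional YAML file whose entries override the defaults.
#' @param overrides optional named list applied last.
#' @return configuration list.
#' @export
pipelineConfig <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1L,
    pedigree = list(nCouples = 150, sibship = c(`1` = 0.3, `2` = 0.45,
                                                `3` = 0.25),
                    nSingletons = 60),
    genome = list(nSnps = 1600, nChromosomes = 4,
                  mafRange = c(0.05, 0.5), ldBlockSize = 4,
                  ldRho = 0.6),
    qc = list(callrateMin = 0.98, indivMissingMax = 0.02,
              mafMin = 0.01, hwePMin = 1e-6),
    trait = list(varG = 0.2, varC = 0.15, nCausal = 200),
    disease = list(varG = 0.25, varF = 0.1, prevalence = 0.162,
                   nCausal = 200),
    rG = 0.33,
    model = list(components = c("G", "K", "F", "C", "S"),
                 alpha = 0.05, nPCs = 4),
    prs = list(clumpR2 = 0.1, clumpKb = 250, nDiscovery = 50000,
               thresholds = seq(0.01, 1, by = 0.01)),
    ldsc = list(windowKb = 1000, nBlocks = 50,
                nDiscovery1 = 20000, nDiscovery2 = 50000))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y)
  }
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Run the full synthetic family study
#'
#' Chains every stage on simulated data with known ground truth:
#' pedigree and genotype simulation, genotype QC, construction of the
#' G/K/F/C/S relationship matrices, backward stepwise variance-component
#' selection for the quantitative trait, polygenic risk scoring of a
#' genetically correlated binary disease (clumping, threshold search,
#' mixed-model association with liability conversion), a
#' leave-one-chromosome-out GWAS of both traits with LD-score-regression
#' genetic correlation, and the phenotypic prevalence / relative-risk /
#' association statistics.  Any stage failure aborts with a
#' stage-named diagnostic.
#'
#' @param config configuration list from [pipelineConfig()] (or a YAML
#'   path).
#' @param outDir optional directory; when given, tables and a JSON
#'   report are written there.
#' @param verbose print stage progress.
#' @return report list with one element per stage.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        verbose = TRUE) {
  if (is.character(config)) config <- pipelineConfig(config)
  cf <- config
  say <- function(...) if (verbose) message("[famvar] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  report <- list(config = cf)

  say("simulate: pedigree, genotypes, trait pair")
  sim <- stage("simulate", {
    ped <- simulatePedigree(cf$pedigree$nCouples, cf$pedigree$sibship,
                            cf$pedigree$nSingletons, seed = cf$seed)
    gm <- simulateGenotypes(ped, cf$genome$nSnps, cf$genome$mafRange,
                            cf$genome$nChromosomes,
                            cf$genome$ldBlockSize, cf$genome$ldRho,
                            seed = cf$seed + 1L)
    pair <- simulateTraitPair(
      ped, gm, rG = cf$rG,
      spec1 = cf$trait[setdiff(names(cf$trait), "nCausal")],
      spec2 = c(cf$disease[setdiff(names(cf$disease), "nCausal")],
                list(binary = TRUE)),
      nCausal = cf$trait$nCausal, seed = cf$seed + 2L)
    list(ped = ped, gm = gm, pair = pair)
  })
  report$pedigree <- pedigreeCounts(sim$ped)

  say("qc: genotype filters")
  qc <- stage("qc", qcGenotypes(sim$gm, cf$qc$callrateMin,
                                cf$qc$indivMissingMax, cf$qc$mafMin,
                                cf$qc$hwePMin, ped = sim$ped))
  report$qc <- qc$report
  gm <- qc$genotypes

  say("relmat: G, K, F, C, S")
  mats <- stage("relmat", {
    env <- buildEnvMatrices(sim$ped)
    list(G = buildGRM(gm), K = buildPedigreeMatrix(sim$ped),
         F = env$F, C = env$C, S = env$S)
  })
  report$matrixNonzero <- lapply(mats, nNonzeroOffdiag)

  y <- sim$pair$pheno1$pheno
  yBin <- sim$pair$pheno2$pheno
  Xc <- stage("covariates", {
    pcs <- grmPrincipalComponents(mats$G, cf$model$nPCs)
    age <- drop(scale(stats::rnorm(length(y), 55, 12)))
    sex <- sim$ped@ped$sex - 1
    cbind(intercept = 1, age = age, sex = sex, pcs)
  })

  say("vcomp: backward stepwise selection")
  sel <- stage("vcomp", stepwiseSelect(
    y, Xc, mats[cf$model$components], alpha = cf$model$alpha))
  report$modelSelection <- list(
    final = sel$final,
    estimates = estimates(sel$fit), se = stdErrors(sel$fit),
    trace = lapply(sel$trace, function(f)
      list(components = setdiff(names(estimates(f)), "E"),
           estimates = estimates(f), waldP = f@waldP, lrtP = f@lrtP)))

  say("prs: clump, score, associate")
  prs <- stage("prs", {
    disco <- simulateDiscoveryStats(
      gm, attr(sim$pair$pheno2, "effects"), cf$prs$nDiscovery,
      seed = cf$seed + 3L)
    cl <- clumpSumstats(disco, gm, cf$prs$clumpR2, cf$prs$clumpKb)
    prof <- scorePRS(gm, cl, cf$prs$thresholds)
    prof <- bestThreshold(prof, y, Xc, mats$K)
    score <- drop(scale(prof@scores[, match(prof@bestThreshold,
                                            prof@thresholds)]))
    aQuant <- prsAssoc(y, score, Xc, mats$K)
    aBin <- prsAssoc(yBin, score, Xc, mats$K)
    lb <- liabilityBeta(aBin$beta, aBin$se,
                        prevalence = cf$disease$prevalence,
                        caseProportion = mean(yBin))
    list(nClumped = nrow(cl), bestThreshold = prof@bestThreshold,
         bestR2 = prof@bestR2, quantitative = aQuant,
         binary = c(aBin, betaLiability = lb$beta,
                    seLiability = lb$se))
  })
  report$prs <- prs

  say("sumstats: LOCO GWAS + LDSC")
  ldscRep <- stage("sumstats", {
    ss1 <- mlmaLoco(y, Xc, gm)
    yb <- drop(scale(yBin))
    ss2 <- mlmaLoco(yb, Xc, gm)
    ld <- ldScores(gm, cf$ldsc$windowKb)
    # the h2 slopes of an LD score regression are unidentifiable at a
    # few hundred cohort samples; like the design it emulates, the
    # genetic-correlation stage pairs discovery-scale statistics (drawn
    # from the polygenic expectation with the panel's LD scores and the
    # configured rG) while the cohort GWAS contributes the inflation
    # diagnostics
    disc <- simulateSumstats(c(cf$ldsc$nDiscovery1, cf$ldsc$nDiscovery2),
                             nrow(ld), h2 = c(cf$trait$varG,
                                              cf$disease$varG),
                             rG = cf$rG, ldScores = ld$ldScore,
                             seed = cf$seed + 4L)
    disc[[1]]$snp <- ld$snp; disc[[2]]$snp <- ld$snp
    rg <- ldscRg(disc[[1]], disc[[2]], ld, cf$ldsc$nBlocks)
    list(lambda1 = genomicInflation(ss1$p),
         lambda2 = genomicInflation(ss2$p), rg = rg)
  })
  report$ldsc <- ldscRep

  say("assoc: prevalence, relative risk, trait association")
  report$assoc <- stage("assoc", {
    exposed <- y > median(y)
    rr <- relativeRisk(sum(yBin[exposed]), sum(exposed),
                       sum(yBin[!exposed]), sum(!exposed))
    ta <- traitAssoc(yBin, y, Xc, mats$K, binary = TRUE,
                     prevalenceK = cf$disease$prevalence)
    list(prevalence = prevalence(yBin), rr = rr[c("rr", "ciLow",
                                                  "ciHigh")],
         traitAssoc = ta)
  })

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePedigreeTable(sim$ped, file.path(outDir, "pedigree.tsv"))
    writePhenoTable(sim$pair$pheno1, file.path(outDir, "trait1.tsv"))
    writePhenoTable(sim$pair$pheno2, file.path(outDir, "trait2.tsv"))
    jsonlite::write_json(
      report[setdiff(names(report), "config")],
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
  }
  report
}

#' Simulate-and-refit study of the two-component couple model
#'
#' Replicates the couple-structured design: each replicate simulates a
#' cohort of couples with two children per family, genotypes in linkage
#' equilibrium, and a phenotype carrying exactly \code{varG} SNP-genetic
#' and \code{varC} couple-environment variance, then refits both
#' fractions with the two-component (G + C) REML model.  Returns the
#' per-replicate estimates; the means recover the generating values and
#' the Monte-Carlo standard error quantifies the replication noise.
#'
#' @param nReps number of replicates (default 20).
#' @param nCouples couples per replicate (default 1000, i.e. 4000
#'   individuals with two children each).
#' @param nSnps SNPs per replicate (default 10000).
#' @param nCausal causal SNPs (default 1000).
#' @param varG,varC generating variance fractions (defaults 0.08 and
#'   0.13).
#' @param seed integer seed; replicate r uses \code{seed + 1000 + r}.
#' @param verbose print per-replicate progress.
#' @return \code{data.frame} with one row per replicate (columns
#'   \code{G}, \code{C}, \code{E}, \code{converged}).
#' @export
componentRecoveryStudy <- function(nReps = 20, nCouples = 1000,
                                   nSnps = 10000, nCausal = 1000,
                                   varG = 0.08, varC = 0.13, seed = 1,
                                   verbose = FALSE) {
  res <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    s <- seed + 1000L + r
    ped <- simulatePedigree(nCouples, 2, seed = s)
    gm <- simulateGenotypes(ped, nSnps, mafRange = c(0.05, 0.5),
                            seed = s + 20000L)
    ph <- simulatePhenotypes(ped, gm, varG = varG, varC = varC,
                             nCausal = nCausal, seed = s + 40000L)
    grm <- buildGRM(gm)
    C <- buildEnvMatrices(ped, "C")$C
    fit <- remlFit(ph$pheno, matrices = list(grm, C))
    est <- estimates(fit)
    res[[r]] <- data.frame(G = est[["G"]], C = est[["C"]],
                           E = est[["E"]], converged = fit@converged)
    if (verbose)
      message(sprintf("replicate %2d: G=%.4f C=%.4f%s", r,
                      est[["G"]], est[["C"]],
                      if (fit@converged) "" else " (not converged)"))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
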