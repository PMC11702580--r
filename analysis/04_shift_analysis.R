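#!/usr/bin/env Rscript
# Stage 4: early-vs-late difference scores around value and identity shifts.
#
# Value shifts (blocks 2/4): firing to delivery of the now-unexpected 2nd
# drop, and in the window where an expected 2nd drop no longer arrives,
# contrasted between the first 5 and last 5 rewarded trials at the shifted
# well. Identity shifts (blocks 3/5): baseline-normalized firing to each
# drop, first 5 trials of the new flavor vs last 5 of the old. Each contrast
# is summarized by its mean score (u) and a two-sided Wilcoxon signed-rank p.

suppressPackageStartupMessages(library(vipe))

all_sum <- list()
for (preset in c("control", "HCx", "OFCx")) {
  sess <- read_session(file.path("results/sessions", preset))
  labels <- read.csv(file.path("results",
                               paste0("unit_labels_", preset, ".csv")))
  resp <- labels$unit_id[labels$label == "dopamine" &
                           labels$reward_responsive %in% TRUE]
  sc <- difference_scores(sess, resp)
  summ <- do.call(rbind, lapply(split(sc, sc$contrast), function(d)
    summarize_scores(d$score, d$contrast[1])))
  summ <- cbind(group = preset, summ)
  all_sum[[preset]] <- summ
  cat(sprintf("\n[%s] difference scores over %d reward-responsive units:\n",
              preset, length(resp)))
  print(summ[, c("contrast", "u", "p", "n_units")], row.names = FALSE)
  write.csv(sc, file.path("results",
                          paste0("difference_scores_", preset, ".csv")),
            row.names = FALSE)

  tc <- identity_shift_timecourse(sess, resp)
  lv <- timecourse_levels(tc)
  cat(sprintf("  identity-shift normalized firing: early %.2f -> post (trials 6-35) %.2f -> late %.2f\n",
              lv[["early"]], lv[["post"]], lv[["late"]]))
  write.csv(tc, file.path("results", paste0("identity_timecourse_", preset,
                                            ".csv")), row.names = FALSE)
}
write.csv(do.call(rbind, all_sum), "results/score_summaries.csv",
          row.names = FALSE)
cat("\nExpected signature: controls shift delivery scores above zero,\n")
cat("omission below, identity contrasts above (all transient); HCx shows no\n")
cat("shifts anywhere; OFCx keeps an attenuated delivery effect, no omission\n")
cat("dip, null identity scores, and persistently elevated post-shift firing.\n")
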