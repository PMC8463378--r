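#!/usr/bin/env Rscript
# Descriptive statistics of the synthetic emergency-operation log:
# counts and percentages by day type and hour, clock-window counts, and
# transfer-time central tendencies.

suppressMessages(library(stroketriage))
dir.create("results", showWarnings = FALSE)

log <- read_oplog("results/inputs/oplog_lueneburg_like.csv")
s <- summarize_oplog(log)

write.csv(s$by_hour, "results/oplog_by_hour.csv", row.names = FALSE)
write.csv(s$by_day_type, "results/oplog_by_day_type.csv", row.names = FALSE)

message(sprintf("%d operations: %d (%d%%) weekday, %d (%d%%) weekend",
                s$n_total, s$by_day_type$n[1], s$by_day_type$percent[1],
                s$by_day_type$n[2], s$by_day_type$percent[2]))
day <- window_count(log, 8, 17, "weekday")
night <- window_count(log, 0, 7, "weekday")
message(sprintf("weekday 08:00-17:00: %d (%d%%); midnight-07:00: %d (%d%%)",
                day$n, day$percent, night$n, night$percent))
wd <- s$by_hour[s$by_hour$day_type == "weekday", ]
message(sprintf("weekday peak: %d operations (%d%%) at %02d:00",
                max(wd$n), wd$percent[which.max(wd$n)],
                wd$hour[which.max(wd$n)]))
message(sprintf("transfer time: mean %.1f min, median %.0f min",
                s$mean_transfer, s$median_transfer))
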