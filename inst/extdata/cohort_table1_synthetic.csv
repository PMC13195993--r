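id,sex,familial,motif_present
DM2-001,M,TRUE,TRUE
DM2-002,M,TRUE,TRUE
DM2-003,M,TRUE,TRUE
DM2-004,M,TRUE,TRUE
DM2-005,M,TRUE,TRUE
DM2-006,M,TRUE,TRUE
DM2-007,M,TRUE,TRUE
DM2-008,M,TRUE,TRUE
DM2-009,M,TRUE,TRUE
DM2-010,M,TRUE,TRUE
DM2-011,M,TRUE,TRUE
DM2-012,M,TRUE,TRUE
DM2-013,M,TRUE,TRUE
DM2-014,M,TRUE,TRUE
DM2-015,M,TRUE,TRUE
DM2-016,M,TRUE,TRUE
DM2-017,M,TRUE,TRUE
DM2-018,M,TRUE,TRUE
DM2-019,M,TRUE,TRUE
DM2-020,M,TRUE,TRUE
DM2-021,M,TRUE,TRUE
DM2-022,M,TRUE,TRUE
DM2-023,M,FALSE,TRUE
DM2-024,M,FALSE,TRUE
DM2-025,M,FALSE,TRUE
DM2-026,M,FALSE,TRUE
DM2-027,M,FALSE,TRUE
DM2-028,M,FALSE,TRUE
DM2-029,M,FALSE,TRUE
DM2-030,M,FALSE,TRUE
DM2-031,M,FALSE,TRUE
DM2-032,M,FALSE,TRUE
DM2-033,M,FALSE,TRUE
DM2-034,M,FALSE,TRUE
DM2-035,M,FALSE,TRUE
DM2-036,M,FALSE,TRUE
DM2-037,M,FALSE,TRUE
DM2-038,M,FALSE,TRUE
DM2-039,M,FALSE,TRUE
DM2-040,F,TRUE,TRUE
DM2-041,F,TRUE,TRUE
DM2-042,F,TRUE,TRUE
DM2-043,F,TRUE,TRUE
DM2-044,F,TRUE,TRUE
DM2-045,F,TRUE,TRUE
DM2-046,F,TRUE,TRUE
DM2-047,F,TRUE,TRUE
DM2-048,F,TRUE,TRUE
DM2-049,F,TRUE,TRUE
DM2-050,F,TRUE,TRUE
DM2-051,F,TRUE,TRUE
DM2-052,F,TRUE,TRUE
DM2-053,F,TRUE,TRUE
DM2-054,F,TRUE,TRUE
DM2-055,F,TRUE,TRUE
DM2-056,F,TRUE,TRUE
DM2-057,F,TRUE,TRUE
DM2-058,F,TRUE,TRUE
DM2-059,F,TRUE,TRUE
DM2-060,F,TRUE,TRUE
DM2-061,F,TRUE,TRUE
DM2-062,F,TRUE,TRUE
DM2-063,F,TRUE,TRUE
DM2-064,F,TRUE,TRUE
DM2-065,F,TRUE,TRUE
DM2-066,F,TRUE,TRUE
DM2-067,F,TRUE,TRUE
DM2-068,F,TRUE,TRUE
DM2-069,F,TRUE,TRUE
DM2-070,F,TRUE,TRUE
DM2-071,F,FALSE,TRUE
DM2-072,F,FALSE,TRUE
DM2-073,F,FALSE,TRUE
DM2-074,F,FALSE,TRUE
DM2-075,F,FALSE,TRUE
DM2-076,F,FALSE,TRUE
DM2-077,F,FALSE,TRUE
DM2-078,F,FALSE,TRUE
DM2-079,F,FALSE,TRUE
DM2-080,F,FALSE,TRUE
DM2-081,F,FALSE,TRUE
DM2-082,F,FALSE,TRUE
DM2-083,F,FALSE,TRUE
DM2-084,F,FALSE,TRUE
DM2-085,F,FALSE,TRUE
DM2-086,F,FALSE,TRUE
DM2-087,F,FALSE,TRUE
DM2-088,F,FALSE,TRUE
DM2-089,M,TRUE,FALSE
DM2-090,M,FALSE,FALSE
DM2-091,F,TRUE,FALSE
DM2-092,F,FALSE,FALSE
DM2-093,F,FALSE,FALSE
DM2-094,F,FALSE,FALSE
DM2-095,F,FALSE,FALSE
DM2-096,F,FALSE,FALSE
DM2-097,F,FALSE,FALSE
DM2-098,F,FALSE,FALSE
DM2-099,F,FALSE,FALSE
DM2-100,F,FALSE,FALSE
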