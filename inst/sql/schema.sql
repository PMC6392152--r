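-- Triple-store schema for lazy SQL-backed experiments.
-- assay: long-format quantifications, one row per (feature, sample) pair.
-- features / samples: keyed annotation tables. Coordinates on the feature
-- table are 1-based closed intervals.

CREATE TABLE features (
    feature_id TEXT PRIMARY KEY,
    symbol     TEXT,
    seqname    TEXT,
    start      INTEGER,
    "end"      INTEGER,
    strand     TEXT
);

CREATE TABLE samples (
    sample_id  TEXT PRIMARY KEY
);

CREATE TABLE assay (
    feature_id TEXT NOT NULL,
    sample_id  TEXT NOT NULL,
    value      REAL,
    PRIMARY KEY (feature_id, sample_id)
);

CREATE INDEX idx_assay_sample ON assay (sample_id);
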