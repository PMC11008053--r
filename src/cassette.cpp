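#include <Rcpp.h>
#include <unordered_set>
#include <string>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};
static const std::string ANCHOR = "TGGT";

// Hamming distance between equal-length strings; caller guarantees lengths.
static inline int ham(const std::string& a, const std::string& b) {
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i)
        if (a[i] != b[i]) ++d;
    return d;
}

// [[Rcpp::export]]
int hamming_cpp(const std::string& a, const std::string& b) {
    if (a.size() != b.size())
        stop("hamming: sequences must have equal length (%d vs %d)",
             (int)a.size(), (int)b.size());
    return ham(a, b);
}

// Anchor search: positions p with >=14 nt upstream and >=30 nt downstream of
// p+4 are valid; exact TGGT matches beat 1-mismatch matches, leftmost wins.
// Returns 0-based position or -1.
// [[Rcpp::export]]
int find_anchor_cpp(const std::string& seq) {
    const int n = (int)seq.size();
    int best1 = -1;
    for (int p = 14; p + 4 + 30 <= n; ++p) {
        int d = 0;
        for (int k = 0; k < 4; ++k)
            if (seq[p + k] != ANCHOR[k]) if (++d > 1) break;
        if (d == 0) return p;
        if (d == 1 && best1 < 0) best1 = p;
    }
    return best1;
}

// Whitelist correction: putative itself if present, else the unique
// vocabulary member at Hamming distance 1; "" if zero or >=2 candidates.
static std::string correct_one(const std::string& put,
                               const std::unordered_set<std::string>& vocab) {
    if (vocab.count(put)) return put;
    std::string hit;
    int nhit = 0;
    std::string cand = put;
    for (size_t i = 0; i < put.size(); ++i) {
        const char orig = cand[i];
        for (int b = 0; b < 4; ++b) {
            if (BASES[b] == orig) continue;
            cand[i] = BASES[b];
            if (vocab.count(cand)) {
                if (++nhit > 1) { cand[i] = orig; return ""; }
                hit = cand;
            }
        }
        cand[i] = orig;
    }
    return nhit == 1 ? hit : "";
}

// [[Rcpp::export]]
CharacterVector correct_barcode_cpp(const std::string& putative,
                                    const CharacterVector& vocabulary) {
    std::unordered_set<std::string> vocab;
    for (R_xlen_t i = 0; i < vocabulary.size(); ++i) {
        std::string w = as<std::string>(vocabulary[i]);
        if (w.size() != putative.size())
            stop("correct_barcode: vocabulary word length %d != putative length %d",
                 (int)w.size(), (int)putative.size());
        vocab.insert(w);
    }
    std::string res = correct_one(putative, vocab);
    if (res.empty()) return CharacterVector::create(NA_STRING);
    return CharacterVector::create(res);
}

// Batch cassette parser. status: 0 = accepted, 1 = no anchor, 2 = rejected
// (correction failed). Correction order follows the retrieval protocol:
// whitelisted pair accepted as-is; a single absent barcode is corrected on
// its own; when both are absent bc14 is corrected first and bc30 only if
// bc14 succeeded.
// [[Rcpp::export]]
DataFrame parse_reads_cpp(const CharacterVector& read2,
                          const CharacterVector& bc14,
                          const CharacterVector& bc30) {
    std::unordered_set<std::string> v14, v30;
    for (R_xlen_t i = 0; i < bc14.size(); ++i)
        v14.insert(as<std::string>(bc14[i]));
    for (R_xlen_t i = 0; i < bc30.size(); ++i)
        v30.insert(as<std::string>(bc30[i]));

    const R_xlen_t n = read2.size();
    IntegerVector status(n), anchor_pos(n), anchor_mm(n);
    CharacterVector out14(n), out30(n);
    LogicalVector cor14(n), cor30(n);

    for (R_xlen_t i = 0; i < n; ++i) {
        std::string seq = as<std::string>(read2[i]);
        int p = find_anchor_cpp(seq);
        anchor_pos[i] = p;
        if (p < 0) {
            status[i] = 1;
            out14[i] = NA_STRING; out30[i] = NA_STRING;
            anchor_mm[i] = NA_INTEGER;
            continue;
        }
        anchor_mm[i] = ham(seq.substr(p, 4), ANCHOR);
        std::string p14 = seq.substr(p - 14, 14);
        std::string p30 = seq.substr(p + 4, 30);
        bool in14 = v14.count(p14) > 0, in30 = v30.count(p30) > 0;
        std::string f14 = p14, f30 = p30;
        bool c14 = false, c30 = false, ok = true;
        if (in14 && in30) {
            // accept as-is
        } else if (in14 && !in30) {
            f30 = correct_one(p30, v30); c30 = true;
            ok = !f30.empty();
        } else if (!in14 && in30) {
            f14 = correct_one(p14, v14); c14 = true;
            ok = !f14.empty();
        } else {
            f14 = correct_one(p14, v14); c14 = true;
            ok = !f14.empty();
            if (ok) {
                f30 = correct_one(p30, v30); c30 = true;
                ok = !f30.empty();
            }
        }
        if (!ok) {
            status[i] = 2;
            out14[i] = NA_STRING; out30[i] = NA_STRING;
            cor14[i] = false; cor30[i] = false;
        } else {
            status[i] = 0;
            out14[i] = f14; out30[i] = f30;
            cor14[i] = c14 && f14 != p14;
            cor30[i] = c30 && f30 != p30;
        }
    }
    return DataFrame::create(
        _["status"] = status,
        _["anchor_pos"] = anchor_pos,
        _["anchor_mismatches"] = anchor_mm,
        _["bc14"] = out14,
        _["bc30"] = out30,
        _["bc14_corrected"] = cor14,
        _["bc30_corrected"] = cor30,
        _["stringsAsFactors"] = false);
}
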