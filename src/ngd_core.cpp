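#include <Rcpp.h>
using namespace Rcpp;

// Adapter/UMI trimming of raw footprint reads.
//
// Read layout: [umi5 (4 nt)][insert][umi3 (6 nt)][constant 3' adapter],
// possibly truncated at the sequencing read length. The adapter is located
// by scanning 5'->3' for the leftmost match of the constant adapter with at
// most `max_mismatch` mismatches; matches truncated by the read end are
// allowed provided the overlap is at least `min_overlap` nt.
//
// status codes: 0 kept, 1 no_adapter, 2 too_short, 3 too_long
// [[Rcpp::export(name = ".trim_reads_cpp")]]
List trim_reads_cpp(CharacterVector reads, std::string adapter,
                    int min_overlap, int max_mismatch,
                    int umi5_len, int umi3_len,
                    int min_insert, int max_insert) {
    int n = reads.size();
    int alen = adapter.size();
    CharacterVector insert(n), umi5(n), umi3(n);
    IntegerVector status(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        int L = s.size();
        int found = -1;
        for (int pos = 0; pos + min_overlap <= L; ++pos) {
            int ov = std::min(alen, L - pos);
            if (ov < min_overlap) break;
            int mm = 0;
            for (int k = 0; k < ov; ++k) {
                if (s[pos + k] != adapter[k]) {
                    if (++mm > max_mismatch) break;
                }
            }
            if (mm <= max_mismatch) { found = pos; break; }
        }
        if (found < 0) {
            status[i] = 1; insert[i] = ""; umi5[i] = ""; umi3[i] = "";
            continue;
        }
        int ins_len = found - umi5_len - umi3_len;
        if (ins_len < min_insert) {
            status[i] = 2;
            insert[i] = ""; umi5[i] = ""; umi3[i] = "";
            continue;
        }
        if (ins_len > max_insert) {
            status[i] = 3;
            insert[i] = ""; umi5[i] = ""; umi3[i] = "";
            continue;
        }
        status[i] = 0;
        umi5[i]   = s.substr(0, umi5_len);
        insert[i] = s.substr(umi5_len, ins_len);
        umi3[i]   = s.substr(found - umi3_len, umi3_len);
    }
    return List::create(_["insert"] = insert, _["umi5"] = umi5,
                        _["umi3"] = umi3, _["status"] = status);
}

// Ungapped placement of a trimmed footprint on a small transcriptome.
//
// At each candidate placement the maximal trailing run of read bases that
// are 'A' and disagree with the reference (or overhang the transcript 3'
// end) is treated as an untemplated poly(A) tail; A's that match the
// reference are templated (maximal templated extension). The tail is only
// honoured when the templated prefix covers >= min_prefix nt; otherwise the
// trailing disagreements count as ordinary mismatches. A placement is valid
// when mismatches <= floor(max_mm_frac * templated_len). The best placement
// maximises the number of matching templated bases; >1 equally best
// placement => multimapped.
//
// tail_allowed = false gives plain full-length matching (contaminant mode).
//
// status: 0 aligned, 1 unaligned, 2 multimapped
// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector refs,
                          double max_mm_frac, int min_prefix,
                          bool tail_allowed) {
    int n = reads.size();
    int ntx = refs.size();
    std::vector<std::string> txs(ntx);
    for (int t = 0; t < ntx; ++t) txs[t] = as<std::string>(refs[t]);

    IntegerVector out_status(n), out_tx(n), out_start(n), out_len(n),
                  out_tail(n), out_mm(n);

    for (int i = 0; i < n; ++i) {
        std::string r = as<std::string>(reads[i]);
        int L = r.size();
        int best_score = -1, best_count = 0;
        int b_tx = -1, b_start = -1, b_len = 0, b_tail = 0, b_mm = 0;
        // early-exit bound: mismatches within the first min_prefix bases can
        // never be absorbed by a tail
        int hard_limit = (int)std::floor(max_mm_frac * L);

        for (int t = 0; t < ntx; ++t) {
            const std::string &x = txs[t];
            int T = x.size();
            int pmax = tail_allowed ? T - std::min(L, min_prefix) : T - L;
            for (int p = 0; p <= pmax; ++p) {
                int m = std::min(L, T - p);      // bases with ref coverage
                if (m < std::min(L, min_prefix)) break;
                // early reject on the un-clippable prefix
                int head = std::min(m, min_prefix);
                int mm_head = 0;
                bool reject = false;
                for (int k = 0; k < head; ++k) {
                    if (r[k] != x[p + k] && ++mm_head > hard_limit) {
                        reject = true; break;
                    }
                }
                if (reject) continue;
                // overhang bases (beyond transcript end) must all be A to
                // be interpretable as tail
                if (m < L) {
                    if (!tail_allowed) continue;
                    bool ok = true;
                    for (int k = m; k < L; ++k)
                        if (r[k] != 'A') { ok = false; break; }
                    if (!ok) continue;
                }
                // maximal trailing run of A-mismatches (the candidate tail)
                int tail = L - m;                 // overhang part
                int idx = m - 1;
                if (tail_allowed) {
                    while (idx >= 0 && r[idx] == 'A' && r[idx] != x[p + idx]) {
                        ++tail; --idx;
                    }
                } else {
                    tail = 0; idx = m - 1;
                }
                int templ = L - tail;
                if (templ < min_prefix) {
                    // tail not honoured; only a fully covered placement can
                    // fall back to all-templated
                    if (m < L) continue;
                    tail = 0; templ = L;
                }
                int mm = 0;
                for (int k = 0; k < templ; ++k)
                    if (r[k] != x[p + k]) ++mm;
                if (mm > (int)std::floor(max_mm_frac * templ)) continue;
                int score = templ - mm;
                if (score > best_score) {
                    best_score = score; best_count = 1;
                    b_tx = t; b_start = p; b_len = templ;
                    b_tail = tail; b_mm = mm;
                } else if (score == best_score) {
                    ++best_count;
                }
            }
        }
        if (best_score < 0) {
            out_status[i] = 1;
            out_tx[i] = NA_INTEGER; out_start[i] = NA_INTEGER;
            out_len[i] = NA_INTEGER; out_tail[i] = NA_INTEGER;
            out_mm[i] = NA_INTEGER;
        } else if (best_count > 1) {
            out_status[i] = 2;
            out_tx[i] = NA_INTEGER; out_start[i] = NA_INTEGER;
            out_len[i] = NA_INTEGER; out_tail[i] = NA_INTEGER;
            out_mm[i] = NA_INTEGER;
        } else {
            out_status[i] = 0;
            out_tx[i] = b_tx + 1;      // 1-based transcript index for R
            out_start[i] = b_start;    // 0-based transcript coordinate
            out_len[i] = b_len;
            out_tail[i] = b_tail;
            out_mm[i] = b_mm;
        }
    }
    return DataFrame::create(
        _["status"] = out_status, _["tx"] = out_tx, _["start"] = out_start,
        _["length"] = out_len, _["untemplated_A"] = out_tail,
        _["mismatches"] = out_mm);
}
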