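// Stage-1 engine: per-read six-frame scan for putative CDR3 spans anchored by
// the conserved cysteine (C) and the chain's terminal residue (F/W), with
// bounded edit-distance matching of the read prefix/suffix against the
// germline anchor-split context strings. One full candidate is reported per
// read (largest total matched context; ties broken by lexicographically
// smallest core, then frame, then span start). Reads matching only one side
// are reported as V-only / J-only partials for the stage-2 overlap merge.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Levenshtein distance between equal-length windows reduces to the Hamming
// count for distances <= 1 (an indel pair already costs 2), so the bounded
// check is a mismatch count. 'X' (ambiguous translation) never matches.
static inline int window_mismatches(const char* a, const char* b, int k, int cap) {
  int m = 0;
  for (int i = 0; i < k; ++i) {
    if (a[i] != b[i] || a[i] == 'X') {
      if (++m > cap) return m;
    }
  }
  return m;
}

struct MatchResult {
  std::vector<int> hits; // indices into the germline context vector
  int best_dist = -1;
  int ctx = 0;           // matched window length of the best hits
};

// Match a read prefix (everything before the C anchor) against the suffixes
// of the V pre-anchor strings. Context window = last min(plen, |vx|) residues
// of each. Requires plen > min_ctx - 1 (i.e. >= min_ctx).
static MatchResult match_side(const char* ctx_str, int clen, bool suffix_side,
                              const std::vector<std::string>& germ, int max_dist) {
  MatchResult res;
  for (size_t g = 0; g < germ.size(); ++g) {
    int k = std::min<int>(clen, (int)germ[g].size());
    if (k <= 0) continue;
    const char* a;
    const char* b;
    if (suffix_side) { // read prefix vs germline suffix (V side)
      a = ctx_str + (clen - k);
      b = germ[g].c_str() + (germ[g].size() - k);
    } else {           // read suffix vs germline prefix (J side)
      a = ctx_str;
      b = germ[g].c_str();
    }
    int d = window_mismatches(a, b, k, max_dist);
    if (d > max_dist) continue;
    if (res.best_dist < 0 || d < res.best_dist) {
      res.best_dist = d;
      res.hits.clear();
      res.hits.push_back((int)g);
      res.ctx = k;
    } else if (d == res.best_dist) {
      res.hits.push_back((int)g);
      if (k > res.ctx) res.ctx = k;
    }
  }
  return res;
}

static std::string join_hits(const std::vector<int>& hits, const CharacterVector& ids) {
  std::string out;
  for (size_t i = 0; i < hits.size(); ++i) {
    if (i) out += ",";
    out += std::string(ids[hits[i]]);
  }
  return out;
}

// frames: list of 6 character vectors (3 forward, 3 reverse-complement frames)
// all of length n_reads. Returns full candidates and one-sided partials.
// [[Rcpp::export]]
List cpp_stage1_chain(List frames, CharacterVector vx_ids, CharacterVector vx,
                      CharacterVector jy_ids, CharacterVector jy,
                      std::string end_residues, int min_core, int max_core,
                      int min_ctx, int max_dist, bool allow_stop) {
  const int n_frames = frames.size();
  if (n_frames != 6) stop("expected 6 frames");
  std::vector<CharacterVector> fr(n_frames);
  for (int f = 0; f < n_frames; ++f) fr[f] = frames[f];
  const int n = fr[0].size();

  std::vector<std::string> vxs(vx.size()), jys(jy.size());
  for (int i = 0; i < vx.size(); ++i) vxs[i] = std::string(vx[i]);
  for (int i = 0; i < jy.size(); ++i) jys[i] = std::string(jy[i]);

  // full candidates (one per read)
  std::vector<int> c_read, c_frame, c_x, c_y, c_ctx;
  std::vector<std::string> c_core, c_vhits, c_jhits;
  // partials
  std::vector<int> vp_read, vp_frame, vp_x, vp_ctx;
  std::vector<std::string> vp_hits;
  std::vector<int> jp_read, jp_frame, jp_y, jp_ctx;
  std::vector<std::string> jp_hits;

  for (int r = 0; r < n; ++r) {
    bool have_full = false;
    int best_ctx = -1, best_frame = -1, best_x = -1, best_y = -1;
    std::string best_core, best_v, best_j;
    // best one-sided evidence across frames
    bool any_v = false, any_j = false;
    int bv_ctx = -1, bv_frame = -1, bv_x = -1;
    std::string bv_hits;
    int bj_ctx = -1, bj_frame = -1, bj_y = -1;
    std::string bj_hits;

    for (int f = 0; f < n_frames; ++f) {
      const char* s = CHAR(STRING_ELT(fr[f], r));
      int len = (int)strlen(s);
      if (len < min_core) continue;

      // candidate anchor positions with enough flanking context in the read
      std::vector<int> cpos, epos;
      for (int i = min_ctx; i < len; ++i) if (s[i] == 'C') cpos.push_back(i);
      for (int j = 0; j + min_ctx < len; ++j)
        if (end_residues.find(s[j]) != std::string::npos) epos.push_back(j);

      // prefix stop counts for O(1) stop-free span checks
      std::vector<int> stops(len + 1, 0);
      for (int i = 0; i < len; ++i) stops[i + 1] = stops[i] + (s[i] == '*');

      // one-sided V evidence: C anchor with a matching prefix; partial core
      // (C..read end) must be stop-free
      for (size_t ci = 0; ci < cpos.size(); ++ci) {
        int x = cpos[ci];
        if (!allow_stop && stops[len] - stops[x] > 0) continue;
        MatchResult mv = match_side(s, x, true, vxs, max_dist);
        if (mv.best_dist < 0) continue;
        any_v = true;
        if (mv.ctx > bv_ctx) {
          bv_ctx = mv.ctx; bv_frame = f; bv_x = x;
          bv_hits = join_hits(mv.hits, vx_ids);
        }
      }
      // one-sided J evidence: terminal anchor with a matching suffix;
      // partial core (read start..anchor) must be stop-free
      for (size_t ei = 0; ei < epos.size(); ++ei) {
        int y = epos[ei];
        if (!allow_stop && stops[y] > 0) continue;
        MatchResult mj = match_side(s + y + 1, len - y - 1, false, jys, max_dist);
        if (mj.best_dist < 0) continue;
        any_j = true;
        if (mj.ctx > bj_ctx) {
          bj_ctx = mj.ctx; bj_frame = f; bj_y = y;
          bj_hits = join_hits(mj.hits, jy_ids);
        }
      }

      // full spans: every (C, F/W) pair within the length bounds
      for (size_t ci = 0; ci < cpos.size(); ++ci) {
        int x = cpos[ci];
        MatchResult mv = match_side(s, x, true, vxs, max_dist);
        if (mv.best_dist < 0) continue;
        for (size_t ei = 0; ei < epos.size(); ++ei) {
          int y = epos[ei];
          int span = y - x + 1;
          if (span < min_core || span > max_core) continue;
          if (!allow_stop && stops[y + 1] - stops[x] > 0) continue;
          MatchResult mj = match_side(s + y + 1, len - y - 1, false, jys, max_dist);
          if (mj.best_dist < 0) continue;
          std::string core(s + x, s + y + 1);
          int ctx = mv.ctx + mj.ctx;
          bool better = !have_full || ctx > best_ctx ||
            (ctx == best_ctx && core < best_core) ||
            (ctx == best_ctx && core == best_core &&
             (f < best_frame || (f == best_frame && x < best_x)));
          if (better) {
            have_full = true;
            best_ctx = ctx; best_frame = f; best_x = x; best_y = y;
            best_core = core;
            best_v = join_hits(mv.hits, vx_ids);
            best_j = join_hits(mj.hits, jy_ids);
          }
        }
      }
    }

    if (have_full) {
      c_read.push_back(r + 1); c_frame.push_back(best_frame);
      c_x.push_back(best_x); c_y.push_back(best_y); c_ctx.push_back(best_ctx);
      c_core.push_back(best_core); c_vhits.push_back(best_v); c_jhits.push_back(best_j);
    } else if (any_v && !any_j) {
      vp_read.push_back(r + 1); vp_frame.push_back(bv_frame);
      vp_x.push_back(bv_x); vp_ctx.push_back(bv_ctx); vp_hits.push_back(bv_hits);
    } else if (any_j && !any_v) {
      jp_read.push_back(r + 1); jp_frame.push_back(bj_frame);
      jp_y.push_back(bj_y); jp_ctx.push_back(bj_ctx); jp_hits.push_back(bj_hits);
    }
  }

  return List::create(
    _["full"] = List::create(
      _["read"] = wrap(c_read), _["frame"] = wrap(c_frame),
      _["x"] = wrap(c_x), _["y"] = wrap(c_y), _["ctx"] = wrap(c_ctx),
      _["core_aa"] = wrap(c_core), _["v_hits"] = wrap(c_vhits),
      _["j_hits"] = wrap(c_jhits)),
    _["v_partial"] = List::create(
      _["read"] = wrap(vp_read), _["frame"] = wrap(vp_frame),
      _["x"] = wrap(vp_x), _["ctx"] = wrap(vp_ctx), _["v_hits"] = wrap(vp_hits)),
    _["j_partial"] = List::create(
      _["read"] = wrap(jp_read), _["frame"] = wrap(jp_frame),
      _["y"] = wrap(jp_y), _["ctx"] = wrap(jp_ctx), _["j_hits"] = wrap(jp_hits))
  );
}
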