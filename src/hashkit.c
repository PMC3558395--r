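/* Batch SHA-256 hashing and big-endian bit-window extraction.
 *
 * The key-synthesis emulation needs tens of millions of truncated digests;
 * looping over R-level hash calls is the bottleneck, so the digest loop and
 * the leading-bit truncation live here.  Hashing itself is OpenSSL's
 * libcrypto (EVP one-shot); nothing cryptographic is reimplemented.
 */
#include <R.h>
#include <Rinternals.h>
#include <string.h>
#include <stdio.h>
#include <openssl/evp.h>

/* Extract consecutive big-endian bit windows from the leading bits of each
 * SHA-256 digest.  widths: integer vector, each 1..53, sum <= 256.  Returns
 * an n x length(widths) numeric matrix; every value is an exact integer
 * < 2^53 so doubles are lossless. */
SEXP C_sha256_windows(SEXP x, SEXP widths)
{
    if (TYPEOF(x) != STRSXP) error("input must be a character vector");
    if (TYPEOF(widths) != INTSXP) error("widths must be an integer vector");
    R_xlen_t n = XLENGTH(x);
    int m = LENGTH(widths);
    const int *w = INTEGER(widths);
    int total = 0;
    for (int j = 0; j < m; j++) {
        if (w[j] < 1 || w[j] > 53) error("each window width must be in 1..53");
        total += w[j];
    }
    if (total > 256) error("window widths exceed the 256-bit digest");

    SEXP ans = PROTECT(allocMatrix(REALSXP, n, m));
    double *out = REAL(ans);
    unsigned char md[EVP_MAX_MD_SIZE];
    unsigned int mdlen;
    const EVP_MD *sha256 = EVP_sha256();

    for (R_xlen_t i = 0; i < n; i++) {
        SEXP s = STRING_ELT(x, i);
        if (s == NA_STRING) {
            for (int j = 0; j < m; j++) out[i + (R_xlen_t)j * n] = NA_REAL;
            continue;
        }
        if (!EVP_Digest(CHAR(s), (size_t)LENGTH(s), md, &mdlen, sha256, NULL))
            error("SHA-256 digest failed");
        int bitpos = 0;
        for (int j = 0; j < m; j++) {
            double v = 0.0;
            for (int b = 0; b < w[j]; b++, bitpos++) {
                int bit = (md[bitpos >> 3] >> (7 - (bitpos & 7))) & 1;
                v = v * 2.0 + bit;
            }
            out[i + (R_xlen_t)j * n] = v;
        }
    }
    UNPROTECT(1);
    return ans;
}

/* Build "prefix<i>suffix" strings for i = from .. from+n-1 (exact doubles).
 * Fast deterministic generator for large synthetic populations. */
SEXP C_counter_strings(SEXP prefix, SEXP suffix, SEXP from, SEXP count)
{
    const char *pre = CHAR(STRING_ELT(prefix, 0));
    const char *suf = CHAR(STRING_ELT(suffix, 0));
    double from_d = REAL(from)[0];
    R_xlen_t n = (R_xlen_t)REAL(count)[0];
    if (n < 0) error("count must be nonnegative");

    SEXP ans = PROTECT(allocVector(STRSXP, n));
    char buf[512];
    size_t maxfix = strlen(pre) + strlen(suf);
    if (maxfix > 460) error("prefix/suffix too long");
    for (R_xlen_t i = 0; i < n; i++) {
        long long v = (long long)(from_d + (double)i);
        int len = snprintf(buf, sizeof buf, "%s%lld%s", pre, v, suf);
        SET_STRING_ELT(ans, i, mkCharLen(buf, len));
    }
    UNPROTECT(1);
    return ans;
}

/* Sign-pattern stereo layers: for each bitmask value in [from, from+n), emit
 * "1s,2s,...,ks" where s is '+' when the corresponding bit of the mask is
 * set, '-' otherwise (bit 1 = element 1 = least significant).  Mirrors an
 * InChI /t layer textually; n_elem <= 40 so masks fit exactly in doubles. */
SEXP C_stereo_layers(SEXP n_elem, SEXP from, SEXP count)
{
    int k = INTEGER(n_elem)[0];
    double from_d = REAL(from)[0];
    R_xlen_t n = (R_xlen_t)REAL(count)[0];
    if (k < 0 || k > 40) error("number of stereogenic elements must be in 0..40");
    if (n < 0) error("count must be nonnegative");

    SEXP ans = PROTECT(allocVector(STRSXP, n));
    char buf[512];
    for (R_xlen_t i = 0; i < n; i++) {
        unsigned long long mask = (unsigned long long)(from_d + (double)i);
        int pos = 0;
        for (int e = 1; e <= k; e++) {
            pos += snprintf(buf + pos, sizeof buf - pos, "%d%c%s",
                            e, (mask >> (e - 1)) & 1ULL ? '+' : '-',
                            e < k ? "," : "");
        }
        SET_STRING_ELT(ans, i, mkCharLen(buf, pos));
    }
    UNPROTECT(1);
    return ans;
}

/* Elementwise concatenation of equal-length character vectors (the hot
 * path assembling millions of block strings from unit-table lookups). */
SEXP C_concat_columns(SEXP cols)
{
    if (TYPEOF(cols) != VECSXP || LENGTH(cols) < 1)
        error("'cols' must be a non-empty list of character vectors");
    int m = LENGTH(cols);
    R_xlen_t n = XLENGTH(VECTOR_ELT(cols, 0));
    for (int j = 0; j < m; j++) {
        SEXP c = VECTOR_ELT(cols, j);
        if (TYPEOF(c) != STRSXP || XLENGTH(c) != n)
            error("all columns must be character vectors of equal length");
    }
    SEXP ans = PROTECT(allocVector(STRSXP, n));
    char buf[512];
    for (R_xlen_t i = 0; i < n; i++) {
        int pos = 0;
        for (int j = 0; j < m; j++) {
            SEXP s = STRING_ELT(VECTOR_ELT(cols, j), i);
            if (s == NA_STRING) error("NA in column %d", j + 1);
            int len = LENGTH(s);
            if (pos + len >= (int)sizeof buf) error("row too long");
            memcpy(buf + pos, CHAR(s), len);
            pos += len;
        }
        SET_STRING_ELT(ans, i, mkCharLen(buf, pos));
    }
    UNPROTECT(1);
    return ans;
}

/* Count overlapping occurrences of fixed patterns across blocks given as
 * unit-index rows, without materializing the block strings.  idx: n x m
 * numeric matrix of 0-based unit indices; tables: list of m character
 * vectors (the unit codecs); patterns: character vector.  Returns one
 * total count per pattern (start positions counted, overlaps included). */
SEXP C_scan_indices(SEXP idx, SEXP tables, SEXP patterns)
{
    if (TYPEOF(idx) != REALSXP) error("'idx' must be a numeric matrix");
    SEXP dim = getAttrib(idx, R_DimSymbol);
    if (TYPEOF(dim) != INTSXP || LENGTH(dim) != 2)
        error("'idx' must be a matrix");
    R_xlen_t n = INTEGER(dim)[0];
    int m = INTEGER(dim)[1];
    if (TYPEOF(tables) != VECSXP || LENGTH(tables) != m)
        error("'tables' must be a list of length ncol(idx)");
    int np = LENGTH(patterns);

    const char ***tab = (const char ***) R_alloc(m, sizeof(char **));
    int *card = (int *) R_alloc(m, sizeof(int));
    int *ulen = (int *) R_alloc(m, sizeof(int));
    int L = 0;
    for (int j = 0; j < m; j++) {
        SEXP t = VECTOR_ELT(tables, j);
        if (TYPEOF(t) != STRSXP || LENGTH(t) < 1)
            error("unit table %d must be a character vector", j + 1);
        card[j] = LENGTH(t);
        ulen[j] = LENGTH(STRING_ELT(t, 0));
        L += ulen[j];
        tab[j] = (const char **) R_alloc(card[j], sizeof(char *));
        for (int v = 0; v < card[j]; v++)
            tab[j][v] = CHAR(STRING_ELT(t, v));
    }
    if (L > 256) error("block too long");

    const char **pat = (const char **) R_alloc(np, sizeof(char *));
    int *plen = (int *) R_alloc(np, sizeof(int));
    for (int p = 0; p < np; p++) {
        pat[p] = CHAR(STRING_ELT(patterns, p));
        plen[p] = LENGTH(STRING_ELT(patterns, p));
    }

    SEXP ans = PROTECT(allocVector(REALSXP, np));
    double *cnt = REAL(ans);
    for (int p = 0; p < np; p++) cnt[p] = 0.0;
    const double *x = REAL(idx);
    char buf[256];

    for (R_xlen_t i = 0; i < n; i++) {
        int pos = 0;
        for (int j = 0; j < m; j++) {
            double vd = x[i + (R_xlen_t)j * n];
            int v = (int) vd;
            if (vd != (double)v || v < 0 || v >= card[j])
                error("index out of range for unit %d", j + 1);
            memcpy(buf + pos, tab[j][v], ulen[j]);
            pos += ulen[j];
        }
        for (int p = 0; p < np; p++) {
            int w = plen[p];
            for (int s = 0; s + w <= L; s++)
                if (memcmp(buf + s, pat[p], w) == 0) cnt[p] += 1.0;
        }
    }
    UNPROTECT(1);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"C_sha256_windows",  (DL_FUNC) &C_sha256_windows,  2},
    {"C_counter_strings", (DL_FUNC) &C_counter_strings, 4},
    {"C_stereo_layers",   (DL_FUNC) &C_stereo_layers,   3},
    {"C_concat_columns",  (DL_FUNC) &C_concat_columns,  1},
    {"C_scan_indices",    (DL_FUNC) &C_scan_indices,    3},
    {NULL, NULL, 0}
};

void R_init_inchikeystats(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
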