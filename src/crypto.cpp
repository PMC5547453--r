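// Thin wrappers over OpenSSL libcrypto (EVP interface): SHA-256, HMAC,
// HKDF, AES-128-GCM, P-256 ECDH key agreement and ECDSA signatures.
// Asymmetric keys travel as DER blobs (PKCS#8 private / SubjectPublicKeyInfo
// public) so R never manipulates curve points directly.
#include <Rcpp.h>
#include <openssl/evp.h>
#include <openssl/hmac.h>
#include <openssl/rand.h>
#include <openssl/kdf.h>
#include <openssl/ec.h>
#include <openssl/obj_mac.h>
#include <openssl/x509.h>
#include <openssl/err.h>

using namespace Rcpp;

static void crypto_fail(const char* what) {
  unsigned long e = ERR_get_error();
  char buf[256];
  ERR_error_string_n(e, buf, sizeof(buf));
  stop(std::string("OpenSSL failure in ") + what + ": " + buf);
}

// [[Rcpp::export(name = ".c_rand_bytes")]]
RawVector c_rand_bytes(int n) {
  RawVector out(n);
  if (n > 0 && RAND_bytes(RAW(out), n) != 1) crypto_fail("RAND_bytes");
  return out;
}

// [[Rcpp::export(name = ".c_sha256")]]
RawVector c_sha256(RawVector data) {
  RawVector out(32);
  unsigned int len = 32;
  if (EVP_Digest(RAW(data), data.size(), RAW(out), &len, EVP_sha256(), NULL) != 1)
    crypto_fail("EVP_Digest");
  return out;
}

// [[Rcpp::export(name = ".c_hmac_sha256")]]
RawVector c_hmac_sha256(RawVector key, RawVector data) {
  RawVector out(32);
  unsigned int len = 32;
  if (HMAC(EVP_sha256(), RAW(key), key.size(), RAW(data), data.size(),
           RAW(out), &len) == NULL)
    crypto_fail("HMAC");
  return out;
}

// [[Rcpp::export(name = ".c_hkdf_sha256")]]
RawVector c_hkdf_sha256(RawVector ikm, RawVector salt, RawVector info, int length) {
  RawVector out(length);
  EVP_PKEY_CTX* ctx = EVP_PKEY_CTX_new_id(EVP_PKEY_HKDF, NULL);
  if (!ctx) crypto_fail("HKDF ctx");
  size_t outlen = (size_t)length;
  bool ok = EVP_PKEY_derive_init(ctx) == 1 &&
    EVP_PKEY_CTX_set_hkdf_md(ctx, EVP_sha256()) == 1 &&
    EVP_PKEY_CTX_set1_hkdf_key(ctx, RAW(ikm), ikm.size()) == 1 &&
    (salt.size() == 0 ||
     EVP_PKEY_CTX_set1_hkdf_salt(ctx, RAW(salt), salt.size()) == 1) &&
    (info.size() == 0 ||
     EVP_PKEY_CTX_add1_hkdf_info(ctx, RAW(info), info.size()) == 1) &&
    EVP_PKEY_derive(ctx, RAW(out), &outlen) == 1;
  EVP_PKEY_CTX_free(ctx);
  if (!ok) crypto_fail("HKDF derive");
  return out;
}

// AES-128-GCM. Returns list(ciphertext, tag); tag is 16 bytes.
// [[Rcpp::export(name = ".c_aes_gcm_encrypt")]]
List c_aes_gcm_encrypt(RawVector key, RawVector iv, RawVector aad, RawVector plaintext) {
  if (key.size() != 16) stop("AES-GCM key must be 16 bytes");
  if (iv.size() != 12) stop("AES-GCM iv must be 12 bytes");
  EVP_CIPHER_CTX* ctx = EVP_CIPHER_CTX_new();
  RawVector ct(plaintext.size());
  RawVector tag(16);
  int len = 0;
  bool ok = EVP_EncryptInit_ex(ctx, EVP_aes_128_gcm(), NULL, NULL, NULL) == 1 &&
    EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_SET_IVLEN, 12, NULL) == 1 &&
    EVP_EncryptInit_ex(ctx, NULL, NULL, RAW(key), RAW(iv)) == 1;
  if (ok && aad.size() > 0)
    ok = EVP_EncryptUpdate(ctx, NULL, &len, RAW(aad), aad.size()) == 1;
  if (ok && plaintext.size() > 0)
    ok = EVP_EncryptUpdate(ctx, RAW(ct), &len, RAW(plaintext), plaintext.size()) == 1;
  if (ok) ok = EVP_EncryptFinal_ex(ctx, RAW(ct) + (plaintext.size() ? len : 0), &len) == 1;
  if (ok) ok = EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_GET_TAG, 16, RAW(tag)) == 1;
  EVP_CIPHER_CTX_free(ctx);
  if (!ok) crypto_fail("AES-GCM encrypt");
  return List::create(_["ciphertext"] = ct, _["tag"] = tag);
}

// Returns plaintext, or NULL when authentication fails (callers raise a
// typed R condition; tag failure is an expected adversarial outcome, not
// an internal error).
// [[Rcpp::export(name = ".c_aes_gcm_decrypt")]]
SEXP c_aes_gcm_decrypt(RawVector key, RawVector iv, RawVector aad,
                       RawVector ciphertext, RawVector tag) {
  if (key.size() != 16) stop("AES-GCM key must be 16 bytes");
  if (iv.size() != 12) stop("AES-GCM iv must be 12 bytes");
  if (tag.size() != 16) return R_NilValue;
  EVP_CIPHER_CTX* ctx = EVP_CIPHER_CTX_new();
  RawVector pt(ciphertext.size());
  int len = 0;
  bool ok = EVP_DecryptInit_ex(ctx, EVP_aes_128_gcm(), NULL, NULL, NULL) == 1 &&
    EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_SET_IVLEN, 12, NULL) == 1 &&
    EVP_DecryptInit_ex(ctx, NULL, NULL, RAW(key), RAW(iv)) == 1;
  if (ok && aad.size() > 0)
    ok = EVP_DecryptUpdate(ctx, NULL, &len, RAW(aad), aad.size()) == 1;
  if (ok && ciphertext.size() > 0)
    ok = EVP_DecryptUpdate(ctx, RAW(pt), &len, RAW(ciphertext), ciphertext.size()) == 1;
  if (ok) {
    RawVector tagcopy = clone(tag);
    ok = EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_SET_TAG, 16, RAW(tagcopy)) == 1 &&
      EVP_DecryptFinal_ex(ctx, RAW(pt) + (ciphertext.size() ? len : 0), &len) == 1;
  }
  EVP_CIPHER_CTX_free(ctx);
  if (!ok) return R_NilValue;
  return pt;
}

static EVP_PKEY* pkey_from_priv_der(RawVector der) {
  const unsigned char* p = RAW(der);
  EVP_PKEY* k = d2i_AutoPrivateKey(NULL, &p, der.size());
  if (!k) crypto_fail("d2i_AutoPrivateKey");
  return k;
}

static EVP_PKEY* pkey_from_pub_der(RawVector der) {
  const unsigned char* p = RAW(der);
  EVP_PKEY* k = d2i_PUBKEY(NULL, &p, der.size());
  if (!k) crypto_fail("d2i_PUBKEY");
  return k;
}

// P-256 keypair as DER blobs.
// [[Rcpp::export(name = ".c_ec_keygen")]]
List c_ec_keygen() {
  EVP_PKEY* pkey = NULL;
  EVP_PKEY_CTX* ctx = EVP_PKEY_CTX_new_id(EVP_PKEY_EC, NULL);
  bool ok = ctx &&
    EVP_PKEY_keygen_init(ctx) == 1 &&
    EVP_PKEY_CTX_set_ec_paramgen_curve_nid(ctx, NID_X9_62_prime256v1) == 1 &&
    EVP_PKEY_keygen(ctx, &pkey) == 1;
  if (ctx) EVP_PKEY_CTX_free(ctx);
  if (!ok) crypto_fail("EC keygen");

  int privlen = i2d_PrivateKey(pkey, NULL);
  int publen = i2d_PUBKEY(pkey, NULL);
  if (privlen <= 0 || publen <= 0) { EVP_PKEY_free(pkey); crypto_fail("i2d"); }
  RawVector priv(privlen), pub(publen);
  unsigned char* pp = RAW(priv);
  i2d_PrivateKey(pkey, &pp);
  pp = RAW(pub);
  i2d_PUBKEY(pkey, &pp);
  EVP_PKEY_free(pkey);
  return List::create(_["private"] = priv, _["public"] = pub);
}

// ECDH shared secret (32 bytes for P-256).
// [[Rcpp::export(name = ".c_ecdh_derive")]]
RawVector c_ecdh_derive(RawVector priv_der, RawVector peer_pub_der) {
  EVP_PKEY* priv = pkey_from_priv_der(priv_der);
  EVP_PKEY* peer = pkey_from_pub_der(peer_pub_der);
  EVP_PKEY_CTX* ctx = EVP_PKEY_CTX_new(priv, NULL);
  size_t slen = 0;
  bool ok = ctx &&
    EVP_PKEY_derive_init(ctx) == 1 &&
    EVP_PKEY_derive_set_peer(ctx, peer) == 1 &&
    EVP_PKEY_derive(ctx, NULL, &slen) == 1;
  RawVector secret(ok ? slen : 0);
  if (ok) ok = EVP_PKEY_derive(ctx, RAW(secret), &slen) == 1;
  if (ctx) EVP_PKEY_CTX_free(ctx);
  EVP_PKEY_free(priv);
  EVP_PKEY_free(peer);
  if (!ok) crypto_fail("ECDH derive");
  return secret;
}

// ECDSA over SHA-256, DER-encoded signature.
// [[Rcpp::export(name = ".c_ecdsa_sign")]]
RawVector c_ecdsa_sign(RawVector priv_der, RawVector msg) {
  EVP_PKEY* priv = pkey_from_priv_der(priv_der);
  EVP_MD_CTX* ctx = EVP_MD_CTX_new();
  size_t siglen = 0;
  bool ok = ctx &&
    EVP_DigestSignInit(ctx, NULL, EVP_sha256(), NULL, priv) == 1 &&
    EVP_DigestSign(ctx, NULL, &siglen, RAW(msg), msg.size()) == 1;
  std::vector<unsigned char> sig(ok ? siglen : 0);
  if (ok) ok = EVP_DigestSign(ctx, sig.data(), &siglen, RAW(msg), msg.size()) == 1;
  if (ctx) EVP_MD_CTX_free(ctx);
  EVP_PKEY_free(priv);
  if (!ok) crypto_fail("ECDSA sign");
  RawVector out(siglen);
  std::copy(sig.begin(), sig.begin() + siglen, RAW(out));
  return out;
}

// [[Rcpp::export(name = ".c_ecdsa_verify")]]
bool c_ecdsa_verify(RawVector pub_der, RawVector msg, RawVector sig) {
  EVP_PKEY* pub = pkey_from_pub_der(pub_der);
  EVP_MD_CTX* ctx = EVP_MD_CTX_new();
  bool ok = ctx &&
    EVP_DigestVerifyInit(ctx, NULL, EVP_sha256(), NULL, pub) == 1 &&
    EVP_DigestVerify(ctx, RAW(sig), sig.size(), RAW(msg), msg.size()) == 1;
  if (ctx) EVP_MD_CTX_free(ctx);
  EVP_PKEY_free(pub);
  return ok;
}
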